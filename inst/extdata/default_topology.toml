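[lipids.DOPC]
headgroup = ["N", "C11", "C12", "C13", "C14", "C15", "P", "O11", "O12", "O13", "O14"]
glycerol = ["C1", "C2", "C3", "O21", "O22", "O31", "O32", "C21", "C31"]
tail = []
is_lipid = true

[lipids.DOPE]
headgroup = ["N", "C11", "C12", "P", "O11", "O12", "O13", "O14"]
glycerol = ["C1", "C2", "C3", "O21", "O22", "O31", "O32", "C21", "C31"]
tail = []
is_lipid = true

[lipids.DOPS]
headgroup = ["N", "C11", "C12", "C13", "O13A", "O13B", "P", "O11", "O12", "O13", "O14"]
glycerol = ["C1", "C2", "C3", "O21", "O22", "O31", "O32", "C21", "C31"]
tail = []
is_lipid = true

[lipids.CHOL]
headgroup = ["O3", "H3'"]
glycerol = []
tail = []
is_lipid = true

[lipids.LPC]
headgroup = ["Q1", "O1"]
glycerol = ["G1"]
tail = ["C1A", "C2A", "C1B", "C2B"]
is_lipid = true

[lipids.LPE]
headgroup = ["Q1", "O1"]
glycerol = ["G1"]
tail = ["C1A", "C2A", "C1B", "C2B"]
is_lipid = true

[lipids.LPS]
headgroup = ["Q1", "O1"]
glycerol = ["G1"]
tail = ["C1A", "C2A", "C1B", "C2B"]
is_lipid = true

[lipids.LST]
headgroup = ["R1", "O1", "HO1"]
glycerol = []
tail = ["E1", "C1A", "C2A"]
is_lipid = true

[lipids.PAT]
headgroup = ["D1"]
glycerol = []
tail = ["C1"]
is_lipid = true

[radii]
H = 0.12
C = 0.17
N = 0.155
O = 0.152
P = 0.18
S = 0.18
Q = 0.75
G = 0.17
R = 0.25
E = 0.6
D = 0.03

[params.LPC.Q1]
charge = 0.3
sigma = 0.47
epsilon = 0.35

[params.LPC.O1]
charge = -0.3
sigma = 0.47
epsilon = 0.35

[params.LPC.G1]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPC.C1A]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPC.C2A]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPC.C1B]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPC.C2B]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPE.Q1]
charge = 0.3
sigma = 0.47
epsilon = 0.35

[params.LPE.O1]
charge = -0.3
sigma = 0.47
epsilon = 0.35

[params.LPE.G1]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPE.C1A]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPE.C2A]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPE.C1B]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPE.C2B]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPS.Q1]
charge = 0.2
sigma = 0.47
epsilon = 0.35

[params.LPS.O1]
charge = -1.2
sigma = 0.47
epsilon = 0.35

[params.LPS.G1]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPS.C1A]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPS.C2A]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPS.C1B]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LPS.C2B]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LST.R1]
charge = 0.2
sigma = 0.47
epsilon = 0.35

[params.LST.O1]
charge = -0.6
sigma = 0.47
epsilon = 0.35

[params.LST.HO1]
charge = 0.4
sigma = 0.04
epsilon = 0.05

[params.LST.E1]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LST.C1A]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.LST.C2A]
charge = 0
sigma = 0.47
epsilon = 0.35

[params.PAT.D1]
charge = 0
sigma = 0.1
epsilon = 0

[params.PAT.C1]
charge = 0
sigma = 0.47
epsilon = 0.35

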