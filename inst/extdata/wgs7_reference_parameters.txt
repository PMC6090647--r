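rs_max = 1.248
Ks = 2
kipa = 5.2957999999999998
kiaa = 60
Yxs = 0.27860000000000001
ms = 0.067900000000000002
K1 = 1.1939
beta_pa = 0.044999999999999998
K2 = 0.059999999999999998
beta_pyr = 0.0035000000000000001
K3 = 0.029999999999999999
K_pyr = 0.29999999999999999
K4 = 1.2974000000000001
beta_aa = 0
K5 = 0.01
K6 = 0
beta_sa = 0.0074000000000000003
K7 = 0.0080000000000000002
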