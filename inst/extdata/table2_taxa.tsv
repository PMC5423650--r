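label	species	genus
P_americana_JX402724	Periplaneta americana	Periplaneta
P_americana_KF640070	Periplaneta americana	Periplaneta
P_americana_KM577024	Periplaneta americana	Periplaneta
P_americana_KM577049	Periplaneta americana	Periplaneta
P_americana_KM577080	Periplaneta americana	Periplaneta
P_americana_KM577135	Periplaneta americana	Periplaneta
P_americana_KM577145	Periplaneta americana	Periplaneta
P_americana_KM577147	Periplaneta americana	Periplaneta
P_americana_KM577150	Periplaneta americana	Periplaneta
P_americana_KM577152	Periplaneta americana	Periplaneta
P_americana_KM577154	Periplaneta americana	Periplaneta
P_americana_KM577156	Periplaneta americana	Periplaneta
P_americana_KM577157	Periplaneta americana	Periplaneta
P_americana_KM577126	Periplaneta americana	Periplaneta
P_australasiae_AM114928	Periplaneta australasiae	Periplaneta
P_australasiae_KX640825	Periplaneta australasiae	Periplaneta
P_brunnea_AM114930	Periplaneta brunnea	Periplaneta
P_fuliginosa_AB126004	Periplaneta fuliginosa	Periplaneta
P_japonica_AM114929	Periplaneta japonica	Periplaneta
P_japonica_JQ350708	Periplaneta japonica	Periplaneta
S_lateralis_NC_030003	Shelfordella lateralis	Shelfordella
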