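pattern_id	class	pattern
ahl_p1	AHL	W-A-x-[DE]-G-F-L-R
ahl_p2	AHL	W-E-[ST]-D-x-L-I-R
ahl_p3	AHL	W-G-R-E-[NQ]-x-F-T
ahl_p4	AHL	W-H-[ILV]-P-E-x-T-G
ahl_p5	AHL	W-K-D-x-[FY]-N-E-L
ahl_p6	AHL	W-L-E-G-x-[RK]-D-S
ahl_p7	AHL	W-N-[DE]-F-T-x-R-A
ahl_p8	AHL	W-P-S-x-E-[LM]-G-K
non_p1	NON_AHL	W-R-T-[ILV]-x-D-N-E
non_p2	NON_AHL	W-S-E-N-x-[FY]-K-D
non_p3	NON_AHL	W-T-G-[DE]-L-x-S-R
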