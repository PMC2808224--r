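# Kinetic parameter set 1 and initial concentrations of the hypoxia-response
# network (dimensionless units).
#
# Mapping assumption: the published parameter table lists twelve values, five
# for single reactions and seven shared by PAIRS of analogous reactions in
# the two oxygen-dependent degradation branches (PHD binding r3/r7, PHD
# release r3/r7 backward, hydroxylation r4/r8, ARNT binding r5/r9, ARNT
# release r5/r9 backward, HRE binding/release r6/r12). This assignment is
# gated by the fixture self-checks: steady-state HIF ~ 140 without oxygen,
# critical oxygen ~ 0.65, and reproduction of the published invariant
# tables. Edit with care: re-run those checks after any change.

[rates]
r1    = 0.2321
r2    = 0.0017
r3_f  = 0.8326
r3_b  = 0.0121
r4    = 0.0361
r5_f  = 0.6163
r5_b  = 0.1693
r6_f  = 0.0566
r6_b  = 0.0196
r7_f  = 0.8326
r7_b  = 0.0121
r8    = 0.0361
r9_f  = 0.6163
r9_b  = 0.1693
r10_f = 0.5722
r10_b = 0.2667
r11   = 0.4591
r12_f = 0.0566
r12_b = 0.0196

[initial]
HIF            = 5   # 0 is equally valid: same steady state (see docs)
ARNT           = 5
HIF_ARNT       = 0
HRE            = 1
HIF_ARNT_HRE   = 0
PHD            = 10
HIF_PHD        = 0
HIFOH          = 0
HIF_ARNT_PHD   = 0
HIFOH_ARNT     = 0
VHL            = 10
HIFOH_VHL      = 0
HIFOH_ARNT_HRE = 0
O2             = 0   # scan variable (held fixed during integration)
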