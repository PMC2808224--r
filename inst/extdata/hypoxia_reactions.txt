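# Hypoxia-response (HIF) switch network: 12 reactions (7 reversible) over
# 13 dynamic species plus the oxygen side condition.
# Oxygen enters only as a read arc: it gates the two hydroxylation steps
# but is never consumed, so its concentration is an external condition.
r1:  -> HIF ; kf=0.2321                                    # constitutive HIF production
r2:  HIF -> ; kf=0.0017                                    # oxygen-independent degradation
r3:  HIF + PHD <-> HIF_PHD ; kf=0.8326, kb=0.0121          # prolyl-hydroxylase binding
r4:  HIF_PHD + O2(read) -> HIFOH + PHD ; kf=0.0361         # hydroxylation (O2-gated)
r5:  HIF + ARNT <-> HIF_ARNT ; kf=0.6163, kb=0.1693        # ARNT subunit binding
r6:  HIF_ARNT + HRE <-> HIF_ARNT_HRE ; kf=0.0566, kb=0.0196
r7:  HIF_ARNT + PHD <-> HIF_ARNT_PHD ; kf=0.8326, kb=0.0121
r8:  HIF_ARNT_PHD + O2(read) -> HIFOH_ARNT + PHD ; kf=0.0361
r9:  HIFOH + ARNT <-> HIFOH_ARNT ; kf=0.6163, kb=0.1693
r10: HIFOH + VHL <-> HIFOH_VHL ; kf=0.5722, kb=0.2667      # von Hippel-Lindau capture
r11: HIFOH_VHL -> VHL ; kf=0.4591                          # proteasomal degradation
r12: HIFOH_ARNT + HRE <-> HIFOH_ARNT_HRE ; kf=0.0566, kb=0.0196
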