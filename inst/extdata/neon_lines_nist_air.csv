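wavelength_nm,uncertainty_nm,label
585.24878,0.00001,Ne I
588.18950,0.00001,Ne I
594.48340,0.00001,Ne I
597.55343,0.00001,Ne I
602.99968,0.00001,Ne I
607.43376,0.00001,Ne I
609.61630,0.00001,Ne I
614.30627,0.00001,Ne I
616.35937,0.00001,Ne I
621.72812,0.00001,Ne I
626.64952,0.00001,Ne I
630.47893,0.00001,Ne I
633.44276,0.00001,Ne I
638.29914,0.00001,Ne I
640.22480,0.00001,Ne I
650.65277,0.00001,Ne I
653.28824,0.00001,Ne I
659.89528,0.00001,Ne I
667.82766,0.00001,Ne I
671.70430,0.00001,Ne I
692.94672,0.00001,Ne I
703.24128,0.00001,Ne I
717.39380,0.00001,Ne I
724.51665,0.00001,Ne I
743.88981,0.00001,Ne I
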