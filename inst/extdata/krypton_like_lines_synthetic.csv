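# Synthetic 12-line list spanning the 530-610 nm transmission band.
# These are NOT measured krypton wavelengths; they emulate a krypton-like
# lamp for exercising the transmission configuration without real data.
wavelength_nm,uncertainty_nm,label
535.400,,synthetic
541.850,,synthetic
548.600,,synthetic
554.950,,synthetic
561.300,,synthetic
568.150,,synthetic
574.800,,synthetic
581.450,,synthetic
588.200,,synthetic
594.750,,synthetic
601.300,,synthetic
607.900,,synthetic
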