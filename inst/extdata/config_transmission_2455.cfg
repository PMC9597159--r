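# 85 mm lens spectrometer with a fixed volume-phase holographic transmission
# grating at 45 degrees to the optical axis, capturing the n = +1 order.
# In this package's sign convention the incident-angle term of the symmetric
# Bragg transmission geometry enters with sign -1 (see the methods vignette),
# which places the modeled band at ~528-617 nm.
label = transmission_2455
focal_length_mm = 85
pixel_pitch_um = 26
grating_lines_per_mm = 2455
half_deviation_deg = 45
grating_angle_deg = 0
grating_type = transmission
diffraction_order = 1
n_pixels = 1024
center_offset_um = 0
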