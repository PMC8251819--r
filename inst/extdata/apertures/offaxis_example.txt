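# Example off-axis MLC aperture, mm at the isocenter plane.
# One rectangle per line: xmin xmax ymin ymax.
# The published off-axis test aperture is shown only pictorially; this
# shipped shape (a 66 x 66 mm opening displaced 50 mm crossline and an
# adjacent narrow strip) is an approximation for exercising off-axis
# collimation, not a reproduction of the clinical shape.
17 83 -33 33
-16 16 -16 50
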