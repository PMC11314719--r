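# Example camera calibration for the marker-based depth pipeline.
focal_px: 600            # pixel focal length at the ideal resolution
principal_point: [352, 352]
ideal_resolution: [704, 704]
window_resolution: [352, 352]
marker_length_cm: 33.40
marker_width_cm: 3.80
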