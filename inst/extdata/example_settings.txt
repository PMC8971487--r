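# Suggested analysis settings for a guinea-pig whole-heart recording.
# Same key = value syntax as the per-dataset settings files; keys are
# validated against omapr::config_registry().
tophat_ms = 200
apd_level = 80
activation_mode = midpoint
cv_window = 5
speed_caps = 1,200
df_band = 0.5,50
df_resolution = 0.05
pcl_tolerance_ms = 5
mask_fraction = 0.3
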