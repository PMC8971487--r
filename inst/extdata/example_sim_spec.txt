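# Synthetic mouse-whole-heart-like recording: planar wave, one pacing
# cycle length.  Consumed by omapr::simulate_cmd() or the CLI
# (`omapr.R simulate --spec ... --out ...`).
grid = 51,51
pixel_size = 156
frame_rate = 1000
geometry = planar
origin = 0
speed = 50
pcl_schedule = 110x12
apd80 = 45
alternans_delta = 0
upstroke_ms = 4
noise_sd = 0.05
polarity = inverted_voltage
seed = 1
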