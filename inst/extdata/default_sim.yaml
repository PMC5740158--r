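# Default synthetic Hi-C conditions: 10 Mb chromosome at 40 Kb
# resolution, contiguous domains of 200 Kb - 2 Mb with bi-linear
# power-law decay (breakpoint 150 - 350 Kb), weaker inter-domain
# decay, Poisson count noise.
n_bins: 250
resolution: 40000
tad_size_bins: [5, 50]
decay:
  intra_I1: [80.0, 150.0]
  intra_slope: [-1.2, -0.7]
  bilinear: true
  breakpoint_bp: [150000.0, 350000.0]
  slope2_delta: [0.3, 0.7]
sky:
  slope: -1.4
  I1: 25.0
noise: poisson
depth: 1.0
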