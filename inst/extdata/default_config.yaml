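# Example run configuration: 20 um particles in 0.1 wt% hyaluronic acid /
# PBS, dispersed into mineral oil at a 100 x 100 um T-junction.

geometry:
  W_um: 100          # channel width, micrometres
  H_um: 100          # channel depth, micrometres

fluids:
  mu_c_Pa_s: 0.029   # continuous-phase (mineral oil) viscosity, Pa s
  gamma_N_m: 3.35e-3 # interfacial tension, N/m
  lambda_s: 7.27e-3  # dispersed-phase relaxation time, s (metadata)
  dispersed_label: "hyaluronic acid 0.1 wt% in PBS"

particle:
  d_m: 20.0e-6       # particle diameter, metres
  u_m_s: 0.01        # particle velocity, m/s (measured; plug_flow_velocity()
                     # gives an estimate if unknown)
  phi: 0.002         # bulk volume fraction (metadata)

train:
  phi_l: 0.1              # local linear concentration N d / L
  gap_cv: 0.25            # gap coefficient of variation: 0 = perfect train,
                          # 1 = fully stochastic (Poisson) arrivals
  aggregate_fraction: 0.1 # residual doublet probability per arrival

laws:
  frequency: {A: 1.64, B: 0.6666666666666666}  # f_d = A (Q_d Q_c)^B, Q in uL/min
  length: {intercept: 1.0, slope: 2.0}         # L/W = 1 + 2 Q_d/Q_c

simulation:
  f_d_Hz: 50         # droplet frequency; alternatively give
                     # flow_pair: {Q_d: 8, Q_c: 8} to evaluate the law
  duration_s: 100    # simulated time span, s
  seed: 42

output:
  dir: "."
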