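# Treatment-level generating parameters used across tests: the copper/zinc
# co-contamination series for sulfadiazine in a soda saline-alkali wetland
# soil (batch isotherm constants, column hydraulics, two-site sorption).

trt_freundlich <- list(
  CK     = c(kf = 0.181, inv_n = 0.952),
  Cu10   = c(kf = 0.156, inv_n = 1.015),
  Zn100  = c(kf = 0.276, inv_n = 0.851),
  CuZn   = c(kf = 0.175, inv_n = 0.863))

trt_langmuir <- list(
  CK     = c(kl = 0.004, qmax = 40.978),
  Zn100  = c(kl = 0.010, qmax = 20.870))

trt_two_site <- list(
  CK     = c(f = 0.292, kd = 0.318, alpha = 0.001),
  Cu300  = c(f = 0.554, kd = 0.285, alpha = 0.003),
  CuZn   = c(f = 0.292, kd = 0.205, alpha = 0.027))

ref_column <- function() soil_column(length_cm = 15, diameter_cm = 5,
                                     bulk_density = 1.34, theta = 0.42)
ref_hydraulics <- function() hydraulics(v = 4.370, dispersivity = 0.176)

sdz_pulse <- function() pulse_schedule(c_in = 1, pulse_pv = 3, total_pv = 8)
tracer_pulse <- function() pulse_schedule(c_in = 1, pulse_pv = 5, total_pv = 8)

batch_ce_levels <- c(2, 5, 10, 15, 20)
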