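# Default synthetic-cohort configuration.
#
# Parameter distributions and gaze logit constants were calibrated once, by
# coarse grid search over the generator itself, so that a default cohort
# reproduces the study's aggregate statistics: ~23% mean cooperation and
# first-fixation marginals of ~68% top row, ~59% left column, ~72% own
# payoffs (measured on the first fixation kept by the >100 ms filter).
cohort:
  n_participants: 88
  seed: 20260923
  alpha: {shape1: 5.0, shape2: 25.0}         # other-regarding preference ~ Beta
  belief: {shape1: 2.0, shape2: 4.0}         # belief opponent cooperates ~ Beta
  rho: {mean: 1.0, sd: 0.15, lower: 0.5, upper: 1.5}  # risk curvature, truncated normal
  beta: {meanlog: -1.05, sdlog: 0.3, upper: 20}       # inverse temperature ~ log-normal
  gaze_causal_bonus: 0.0                     # optional dwell-on-other -> delta-U bonus (stress mode)
  gaze_seq_bonus: 0.0                        # optional bonus when other's reward is sampled second (stress mode)
gaze:
  b_row: 0.84          # top-row first-fixation logit bias
  b_col: 0.41          # left-column logit bias
  b_self: 1.54         # own-payoff logit bias
  b_val: 0.80          # salience weight per normalized payoff (payoff / 40)
  alpha_gaze_coupling: 3.0   # logit shift toward "other" AOIs per unit alpha
  transition_weights:        # move-type kernel for fixations 2..n
    lateral: 0.30            # same row, other column, same person
    vertical: 0.30           # other row, same column, same person
    diagonal: 0.10           # other row and column, same person
    within_cell: 0.20        # same cell, self <-> other
    diagonal_between: 0.10   # other row, column and person
  n_fix_mean: 6.0      # mean fixations per trial (geometric, min 1)
  n_fix_max: 40
  dur_meanlog: 5.5215  # log(250 ms): median kept-fixation duration
  dur_sdlog: 0.4
  min_dur_ms: 100      # kept fixations are strictly longer than this
  noise_share: 0.1     # share of sub-threshold noise fixations
  noise_range_ms: [30.0, 100.0]
  motor_ms: 300        # added to summed fixation time to form the trial RT
  screen: [1920, 1080]
  inset_x: 60
  inset_y: 70
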