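# Independent oracles frozen from hand algebra (derived from the model
# assumptions, not from the tree engine).
#
# At the base-case parameter values every strategy's expected cost is
# affine in the pretest probability P:
#   PSG first:       555    + 66.6        P
#   LII first:       383.25 + 66.6        P   (= K + JC + CABP at D = 0)
#   LIII then PSG:   722    - 230.6025    P
#   LIII then LII:   550.25 - 138.630375 P
ref_affine <- list(
  psg_first   = c(intercept = 555,    slope =   66.6),
  l2_first    = c(intercept = 383.25, slope =   66.6),
  l3_then_psg = c(intercept = 722,    slope = -230.6025),
  l3_then_l2  = c(intercept = 550.25, slope = -138.630375)
)

ref_cost <- function(algorithm, P) {
  a <- ref_affine[[algorithm]]
  unname(a["intercept"] + a["slope"] * P)
}

# a fully random but valid parameter set (costs on a realistic scale)
random_parameters <- function() {
  model_parameters(
    cpap_nonresponse_frac = runif(1),
    repeat_psg_frac = runif(1),
    psg_cost = runif(1, 0, 1000),
    cpap_trial_cost = runif(1, 0, 200),
    l3_failure_rate = runif(1),
    l3_sensitivity = runif(1),
    l3_specificity = runif(1),
    single_followup_frac = runif(1),
    l3_cost = runif(1, 0, 500),
    l2_failure_rate = runif(1),
    l2_cost = runif(1, 0, 800)
  )
}

# quadratic fit through three (P, cost) points; used to show cost curves
# carry no P^2 term and to predict unseen points exactly
quad_fit <- function(P, y) solve(outer(P, 0:2, `^`), y)
quad_eval <- function(coef, P) drop(outer(P, 0:2, `^`) %*% coef)
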