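## independent oracles used across the suite

## steady state of a linear interconversion chain: Q[i, j] = rate j -> i
## (off-diagonal); returns the stationary distribution
chain_steady <- function(rates) {
  n <- nrow(rates)
  Q <- rates
  diag(Q) <- 0
  diag(Q) <- -colSums(Q)
  A <- rbind(Q[-n, , drop = FALSE], rep(1, n))
  b <- c(rep(0, n - 1), 1)
  solve(A, b)
}

## one-step activation chain oracle: states (inactive, active)
oracle_one_step <- function(v_act, v_inact) {
  rates <- matrix(0, 2, 2)
  rates[2, 1] <- v_act
  rates[1, 2] <- v_inact
  chain_steady(rates)[2]
}

## two-site distributive phosphorylation oracle: three forms with binomial
## site degeneracy (forward 2v, v; backward v, 2v); fully phosphorylated
## fraction
oracle_two_step <- function(v_act, v_inact) {
  rates <- matrix(0, 3, 3)
  rates[2, 1] <- 2 * v_act
  rates[3, 2] <- v_act
  rates[2, 3] <- 2 * v_inact
  rates[1, 2] <- v_inact
  chain_steady(rates)[3]
}

random_network_state <- function() {
  s <- stats::runif(13, 0, 1.5)
  names(s) <- state_names()
  s
}

## cached expensive reference objects, computed once per test run
ref_params <- default_parameters()

cached <- new.env()
get_g2 <- function() {
  if (is.null(cached$g2)) cached$g2 <- g2_state(ref_params)
  cached$g2
}
get_wt_traj <- function() {
  if (is.null(cached$wt)) {
    cached$wt <- simulate_maturation(ref_params, input_step(1),
                                     horizon = 60, init = get_g2())
  }
  cached$wt
}
get_wt_features <- function() mpf_features(get_wt_traj())
get_diagram <- function() {
  if (is.null(cached$bd)) cached$bd <- bifurcation_diagram(ref_params)
  cached$bd
}
get_reference <- function() {
  if (is.null(cached$ref)) {
    bd <- get_diagram()
    cached$ref <- structure(list(
      params = ref_params, features = get_wt_features(),
      P_I = bd$P_I, P_IV = bd$P_IV,
      fold_I = bd$fold_I_state, fold_IV = bd$fold_IV_state,
      amplitude = 1, horizon = 60
    ), class = "meio_reference")
  }
  cached$ref
}
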