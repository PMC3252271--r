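test_that("continuation and fold detection recover a closed-form fold", {
  ## dx/dt = q - x^2: equilibria x = +/- sqrt(q), fold exactly at q = 0
  fun <- function(x, q) q - x[1]^2
  br <- continue_branch(fun, 1, 1, q_range = c(-1, 2), direction = -1,
                        h0 = 0.05, h_max = 0.1, tol = 1e-12)
  folds <- detect_folds(br, fun, tol = 1e-12)
  expect_equal(nrow(folds), 1)
  expect_lt(abs(folds$q[1]), 1e-6)
  expect_lt(abs(folds$state[[1]][1]), 1e-4)
  ## the branch traverses the fold: both stable and unstable points present
  expect_true(any(br$stable) && any(!br$stable))
})

test_that("a monotone branch has no folds", {
  fun <- function(x, q) q - x[1]
  br <- continue_branch(fun, 1, 1, q_range = c(0, 3), direction = 1,
                        h0 = 0.05, h_max = 0.2, tol = 1e-12)
  expect_equal(nrow(detect_folds(br, fun)), 0)
})

test_that("every accepted continuation point satisfies the residual bound", {
  fun <- function(x, q) c(q - x[1]^2 + 0.1 * x[2], -x[2] + 0.5 * x[1])
  br <- continue_branch(fun, c(1, 0.5), 0.95, q_range = c(-1, 2),
                        direction = -1, h0 = 0.02, tol = 1e-11)
  res <- vapply(seq_len(nrow(br)), function(i) {
    sqrt(sum(fun(br$state[[i]], br$q[i])^2))
  }, numeric(1))
  expect_lt(max(res), 1e-9)
})

test_that("two stable equilibria coexist at zero progesterone", {
  eqs <- find_equilibria(ref_params, progesterone = 0, n_starts = 20,
                         seed = 1)
  expect_gte(sum(eqs$stable), 2)
  expect_true(all(eqs$residual < 1e-9))
  stable <- eqs[eqs$stable, ]
  expect_lt(min(stable$mpf_a), 0.05)     # G2 branch
  expect_gt(max(stable$mpf_a), 0.5)      # MII branch
})

test_that("far above the bistable range a single stable state remains", {
  eqs <- find_equilibria(ref_params, progesterone = 3, n_starts = 20,
                         seed = 2)
  expect_equal(sum(eqs$stable), 1)
  expect_gt(eqs$mpf_a[eqs$stable], 0.5)
})

test_that("stability flags agree with direct simulation near equilibria", {
  set.seed(31)
  eqs <- find_equilibria(ref_params, progesterone = 0, n_starts = 10,
                         seed = 3)
  stable <- eqs[eqs$stable, ]
  for (i in seq_len(min(2, nrow(stable)))) {
    x0 <- stable$state[[i]] + runif(13, -1e-3, 1e-3)
    x0 <- pmax(x0, 0)
    f <- function(t, y, parms) meiotic_rhs(t, y, parms, 0)
    sol <- deSolve::lsoda(x0, c(0, 100), f, ref_params,
                          rtol = 1e-9, atol = 1e-11)
    final <- sol[nrow(sol), state_names()]
    expect_lt(sqrt(sum((final - stable$state[[i]])^2)), 1e-4)
  }
})

test_that("the G2 branch turns at a positive fold and continues unstable", {
  bd <- get_diagram()
  g2f <- bd$folds[bd$folds$branch == "g2", ]
  expect_gte(nrow(g2f), 1)
  expect_gt(g2f$q[1], 0)
  g2pts <- bd$points[bd$points$branch == "g2", ]
  expect_true(any(!g2pts$stable))
  ## fold cross-checked by a near-zero leading eigenvalue
  expect_lt(min(bd$folds$eig_min_abs_re), 1e-3)
})

test_that("the MII branch extends to negative progesterone before turning", {
  bd <- get_diagram()
  expect_lt(bd$P_IV, 0)
  expect_gt(bd$P_I, 0)
})
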