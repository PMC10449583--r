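# Shared fixtures: a small phantom and gradient schemes built in code.

small_spec <- function(grid = 16L)
  phantom_spec(grid_shape = rep(grid, 3L), radii = list(wm = 4, gm = 5.5, csf = 7))

# n_dw diffusion volumes at one b-value with b0s interleaved so the first and
# last volumes are b0 (anchors for drift interpolation)
interleaved_scheme <- function(n_dw = 12L, b = 1000, n_b0 = 3L, seed = 1L,
                               b0_threshold = 50) {
  n <- n_dw + n_b0
  pos <- unique(round(seq(1, n, length.out = n_b0)))
  bvals <- numeric(n)
  vecs <- matrix(0, 3, n)
  dw <- setdiff(seq_len(n), pos)
  bvals[dw] <- b
  vecs[, dw] <- sample_directions(n_dw, seed)
  gradient_table(bvals, vecs, b0_threshold)
}

# independent FA oracle: pairwise-difference form, algebraically equivalent to
# the deviation-from-MD form used by the implementation
fa_pairwise <- function(lam) {
  num <- (lam[1] - lam[2])^2 + (lam[2] - lam[3])^2 + (lam[3] - lam[1])^2
  den <- 2 * sum(lam^2)
  if (den == 0) 0 else sqrt(num / den)
}

# closed-form DWI signal, written independently of simulate_dwi
signal_oracle <- function(s0, D, b, g) {
  if (b == 0 || sum(g^2) == 0) return(s0)
  s0 * exp(-b * as.numeric(t(g) %*% D %*% g))
}

random_spd_tensor <- function() {
  A <- matrix(stats::rnorm(9, sd = 1), 3, 3)
  D <- crossprod(A)
  D <- D / max(eigen(D, only.values = TRUE)$values) * stats::runif(1, 5e-4, 2.5e-3)
  D + diag(3) * 1e-5 * 1e-3
}

# Hand-derived ladder sequence (one step per priority item, cycling):
# used to check maximality of plan_diamond independently of its internals.
.ladder_states <- list(
  list(f = 1L, m = "stick",    fw = FALSE, rh = FALSE),  # 4
  list(f = 1L, m = "cylinder", fw = FALSE, rh = FALSE),  # 5
  list(f = 2L, m = "cylinder", fw = FALSE, rh = FALSE),  # 10
  list(f = 2L, m = "cylinder", fw = TRUE,  rh = FALSE),  # 12
  list(f = 3L, m = "cylinder", fw = TRUE,  rh = FALSE),  # 17
  list(f = 3L, m = "tensor",   fw = TRUE,  rh = FALSE),  # 23
  list(f = 3L, m = "tensor",   fw = TRUE,  rh = TRUE))   # 26

ladder_pos <- function(p) {
  for (i in seq_along(.ladder_states)) {
    s <- .ladder_states[[i]]
    if (s$f == p$n_fascicles && s$m == p$fascicle_model &&
        s$fw == p$free_water && s$rh == p$restriction_hindrance)
      return(i)
  }
  stop("plan state not on the ladder")
}

# budget of the state one reduction step earlier (the one the ladder undid last)
undo_budget <- function(p) {
  i <- ladder_pos(p)
  s <- .ladder_states[[i + 1L]]
  diamond_budget(s$f, s$m, s$fw, s$rh)
}

# budget of the next increase step, NA when the ladder is exhausted
next_increase_budget <- function(p) {
  i <- ladder_pos(p)
  if (i >= length(.ladder_states)) return(NA_integer_)
  s <- .ladder_states[[i + 1L]]
  diamond_budget(s$f, s$m, s$fw, s$rh)
}
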