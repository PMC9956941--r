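# Brute-force Shapley oracle for tree ensembles, independent of the
# polynomial-time implementation: enumerates all feature subsets and uses the
# path-dependent conditional-expectation value function (unknown features
# split proportionally to node covers).

# expected tree output given that features in S (1-based indices) are known
oracle_cond_exp <- function(tr, x, S) {
  rec <- function(i) {            # i is a 1-based node index
    if (tr$left[i] < 0) return(tr$value[i])
    f <- tr$var[i] + 1
    l <- tr$left[i] + 1
    r <- tr$right[i] + 1
    if (f %in% S) {
      gl <- if (tr$le) x[f] <= tr$split[i] else x[f] < tr$split[i]
      rec(if (gl) l else r)
    } else {
      (tr$cover[l] * rec(l) + tr$cover[r] * rec(r)) / tr$cover[i]
    }
  }
  rec(1)
}

# exact Shapley values by subset enumeration (feasible for p <= ~8)
oracle_shap <- function(trees, x, p) {
  v <- function(S) sum(vapply(trees, oracle_cond_exp, numeric(1), x = x, S = S))
  phi <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(integer(0)) else
        utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in subsets) phi[i] <- phi[i] + w * (v(c(S, i)) - v(S))
    }
  }
  phi
}

# hand-buildable tree in the package's flat representation
make_tree <- function(left, right, var, split, value, cover,
                      le = TRUE, f32 = FALSE) {
  list(left = as.integer(left), right = as.integer(right),
       var = as.integer(var), split = as.numeric(split),
       value = as.numeric(value), cover = as.numeric(cover),
       le = le, f32 = f32)
}
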