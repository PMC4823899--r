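# Independent oracles and small fixture builders used across the suite.

aa20 <- aa_alphabet()

# Exhaustive global-alignment score by recursive enumeration over all
# monotone alignments with affine gap costs (gap of length g costs
# open + g * ext).  Exponential; only for short sequences.
brute_force_align_score <- function(a, b, subst, open = 10, ext = 1) {
  av <- strsplit(a, NULL)[[1]]
  bv <- strsplit(b, NULL)[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > n && j > m) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, score + subst[av[i], bv[j]], "m")
    if (i <= n)
      rec(i + 1L, j, score - ext - (if (prev == "x") 0 else open), "x")
    if (j <= m)
      rec(i, j + 1L, score - ext - (if (prev == "y") 0 else open), "y")
  }
  rec(1L, 1L, 0, "m")
  best
}

# Tree likelihood by exhaustive enumeration over all ancestral states,
# written against the closed-form machinery in the models module (never
# against the pruning engine it checks).  Supports the two shapes the
# oracle suite uses: a 3-leaf star and the 4-leaf tree ((a,b):t5,c,d).
enum_loglik_star3 <- function(aln, lengths, model) {
  q <- build_rate_matrix(model)
  rc <- rate_categories(model)
  st <- lapply(aln, function(s) match(strsplit(s, NULL)[[1]], aa20))
  pi <- model$frequencies
  total <- 0
  nsites <- length(st[[1]])
  for (site in seq_len(nsites)) {
    lik <- 0
    for (ci in seq_along(rc$rates)) {
      p <- lapply(lengths, function(t) transition_matrix(q, t, rc$rates[ci]))
      s <- 0
      for (x in 1:20) {
        term <- pi[x]
        for (leaf in seq_along(aln)) {
          obs <- st[[leaf]][site]
          term <- term * if (is.na(obs)) 1 else p[[leaf]][x, obs]
        }
        s <- s + term
      }
      lik <- lik + rc$weights[ci] * s
    }
    total <- total + log(lik)
  }
  unname(total)
}

enum_loglik_quartet <- function(aln, t_a, t_b, t_int, t_c, t_d, model) {
  q <- build_rate_matrix(model)
  rc <- rate_categories(model)
  st <- lapply(aln, function(s) match(strsplit(s, NULL)[[1]], aa20))
  pi <- model$frequencies
  total <- 0
  for (site in seq_along(st[[1]])) {
    lik <- 0
    for (ci in seq_along(rc$rates)) {
      r <- rc$rates[ci]
      pa <- transition_matrix(q, t_a, r); pb <- transition_matrix(q, t_b, r)
      pint <- transition_matrix(q, t_int, r)
      pc <- transition_matrix(q, t_c, r); pd <- transition_matrix(q, t_d, r)
      obs <- vapply(st, `[[`, 0L, site)
      cond <- function(p, o) if (is.na(o)) rep(1, 20) else p[, o]
      la <- cond(pa, obs[1]); lb <- cond(pb, obs[2])
      lc <- cond(pc, obs[3]); ld <- cond(pd, obs[4])
      s <- 0
      for (x in 1:20) for (y in 1:20)
        s <- s + pi[x] * lc[x] * ld[x] * pint[x, y] * la[y] * lb[y]
      lik <- lik + rc$weights[ci] * s
    }
    total <- total + log(lik)
  }
  unname(total)
}

random_seqs <- function(n, len, seed, gaps = FALSE) {
  set.seed(seed)
  pool <- if (gaps) c(aa20, "-") else aa20
  out <- vapply(seq_len(n), function(i)
    paste(sample(pool, len, replace = TRUE), collapse = ""), character(1))
  names(out) <- paste0("t", seq_len(n))
  out
}
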