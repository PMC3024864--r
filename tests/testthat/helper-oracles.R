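# Independent oracles used across the suite. These deliberately share no
# code with the package internals: structures are enumerated explicitly
# and statistics are accumulated from the enumeration.

oracle_pairable <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

oracle_pair_energy <- function(a, b, model) {
  key <- paste(sort(c(a, b)), collapse = "")
  switch(key, "CG" = model$gc, "AU" = model$au, "GU" = model$gu,
         stop("not pairable"))
}

# Enumerate every legal nested structure of a sequence as a list of pair
# matrices (0-row matrix = open chain). Hairpin loops must contain at
# least model$min_hairpin_loop unpaired bases.
oracle_enumerate <- function(seq, model = mirhairpin::energy_model()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  minl <- model$min_hairpin_loop
  memo <- new.env(parent = emptyenv())
  empty <- matrix(integer(0), ncol = 2)
  rec <- function(i, j) {
    if (j - i < minl + 1) return(list(empty))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)
    for (k in (i + minl + 1):j) {
      if (!oracle_pairable(chars[i], chars[k])) next
      left <- rec(i + 1, k - 1)
      right <- rec(k + 1, j)
      for (a in left) for (b in right) {
        out <- c(out, list(rbind(c(i, k), a, b)))
      }
    }
    memo[[key]] <- out
    out
  }
  structs <- rec(1, n)
  energies <- vapply(structs, function(s) {
    if (nrow(s) == 0) return(0)
    sum(vapply(seq_len(nrow(s)), function(r) {
      oracle_pair_energy(chars[s[r, 1]], chars[s[r, 2]], model)
    }, numeric(1)))
  }, numeric(1))
  rt <- model$gas_constant * model$temperature
  w <- exp(-energies / rt)
  z <- sum(w)
  probs <- matrix(0, n, n)
  for (s in seq_along(structs)) {
    st <- structs[[s]]
    if (nrow(st) > 0)
      for (r in seq_len(nrow(st)))
        probs[st[r, 1], st[r, 2]] <- probs[st[r, 1], st[r, 2]] + w[s]
  }
  list(structures = structs, energies = energies, mfe = min(energies),
       z = z, efe = -rt * log(z), bp_probs = probs / z)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

dinuc_counts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(chars) < 2) return(table(character(0)))
  table(paste0(chars[-length(chars)], chars[-1]))
}

# Literal transcription of the F-score formula, computed with scalar
# loops; independent of the package's vectorized implementation.
oracle_f_score <- function(xp, xn) {
  np <- length(xp); nn <- length(xn)
  xbar <- mean(c(xp, xn)); xbp <- mean(xp); xbn <- mean(xn)
  num <- (xbp - xbar)^2 + (xbn - xbar)^2
  sp <- 0; for (v in xp) sp <- sp + (v - xbp)^2
  sn <- 0; for (v in xn) sn <- sn + (v - xbn)^2
  den <- sp / (np - 1) + sn / (nn - 1)
  if (den == 0) 0 else num / den
}

bp_probs_dense <- function(fold, n) {
  m <- matrix(0, n, n)
  if (nrow(fold$bp_probs) > 0)
    m[cbind(fold$bp_probs$i, fold$bp_probs$j)] <- fold$bp_probs$prob
  m
}

# Two-branch fixture: sequence constructed so every implied pair of the
# structure is legal (pairs (1,21) (2,20) (4,10) (5,9) (12,18) (13,17)).
two_branch_seq <- "GGAGCAAAGCAAGAAACUACCAA"
two_branch_struct <- "((.((...)).((...)).)).."
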