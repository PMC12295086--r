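# Independent oracles and shared fixture builders.

# Horn's quaternion method for optimal-superposition rmsd: an algorithm
# independent of the SVD-based Kabsch implementation under test.
quaternion_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  pc <- sweep(P, 2, colMeans(P))
  qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(pc, qc)
  sxx <- M[1, 1]; sxy <- M[1, 2]; sxz <- M[1, 3]
  syx <- M[2, 1]; syy <- M[2, 2]; syz <- M[2, 3]
  szx <- M[3, 1]; szy <- M[3, 2]; szz <- M[3, 3]
  K <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(pc^2) + sum(qc^2) - 2 * lambda) / n
  sqrt(max(0, msd))
}

# Exhaustive affine-gap global alignment score on tiny strings (Gotoh-style
# recursion written independently of Biostrings), matching the package's
# gap model: a gap of length L costs open + L * extend.
brute_global_score <- function(a, b, submat, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i > n && j > m) {
      0
    } else {
      best <- -Inf
      if (i <= n && j <= m) {
        best <- max(best, submat[av[i], bv[j]] + rec(i + 1, j + 1, "m"))
      }
      if (i <= n) {   # gap in b
        cost <- if (state == "gb") extend else open + extend
        best <- max(best, -cost + rec(i + 1, j, "gb"))
      }
      if (j <= m) {   # gap in a
        cost <- if (state == "ga") extend else open + extend
        best <- max(best, -cost + rec(i, j + 1, "ga"))
      }
      best
    }
    memo[[key]] <- val
    val
  }
  rec(1, 1, "m")
}

# Canonical pucker reference states used across tests.
PUCKER_4C1 <- c(0.57, 0, 0)
PUCKER_OS2 <- c(0.60, 90, 330)
PUCKER_B25 <- c(0.76, 90, 300)

# A 9-site planted fixture (scaffold + soaks) under one seed.
planted_fixture <- function(seed = 42, jitter = 0.3, n_soaks = 3,
                            n_sites = 9, glcn_site = 3) {
  scaf <- toy_scaffold(n_sites, plus1_index = glcn_site)
  placements <- lapply(seq_len(n_sites), function(k) {
    list(what = if (k == glcn_site) "GlcN" else "Man", site = k)
  })
  cx <- make_complex(complex_spec(scaf, placements, n_soaks = n_soaks,
                                  jitter = jitter, seed = seed))
  list(scaffold = scaf, complexes = cx$models, truth = cx$truth)
}

expected_labels_along_arc <- function(n_sites = 9, glcn_site = 3) {
  as.integer(
    c(rev(seq_len(glcn_site - 1) + 1), 1, -seq_len(n_sites - glcn_site)))
}
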