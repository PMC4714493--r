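# Independent pure-R dynamic-programming oracles used to cross-check the
# package's compiled alignment kernels. These re-implement the documented
# scoring and tie-break rules from scratch and share no code with the
# package internals.

ORACLE_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# local profile/sequence Smith-Waterman, affine gaps (open+ext for the
# first gapped position), X scores 0; returns the best score only
oracle_profile_sw <- function(match_scores, protein, gap_open = 11,
                              gap_ext = 1) {
  L <- ncol(match_scores)
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  idx <- match(ch, ORACLE_AA)
  go <- gap_open + gap_ext
  NEG <- -1e30
  M <- matrix(NEG, L + 1, n + 1)
  X <- matrix(NEG, L + 1, n + 1)
  Y <- matrix(NEG, L + 1, n + 1)
  best <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(n)) {
      s <- if (is.na(idx[j])) 0 else match_scores[idx[j], i]
      M[i + 1, j + 1] <- s + max(0, M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - go, X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go, Y[i + 1, j] - gap_ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

oracle_blosum <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# global alignment with free end gaps, affine penalties; mirrors the
# documented deterministic tie-breaks (diagonal > gap-in-b > gap-in-a;
# among co-optimal endpoints the one consuming the most residues wins,
# scanning the bottom row left to right and then the last column)
oracle_pairwise <- function(a, b, gap_open = 11, gap_ext = 1) {
  sub <- oracle_blosum()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av)
  n <- length(bv)
  go <- gap_open + gap_ext
  NEG <- -1e30
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0
  M[, 1] <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- sub[av[i], bv[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - go, X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go, Y[i + 1, j] - gap_ext)
    }
  }
  cellbest <- function(i, j) max(M[i + 1, j + 1], X[i + 1, j + 1],
                                 Y[i + 1, j + 1])
  escore <- -Inf
  ei <- m
  ej <- n
  tol <- 1e-6
  for (j in 0:n) {
    v <- cellbest(m, j)
    if (v > escore + tol || (v > escore - tol && m + j > ei + ej)) {
      escore <- v
      ei <- m
      ej <- j
    }
  }
  for (i in 0:(m - 1)) {
    v <- cellbest(i, n)
    if (v > escore + tol || (v > escore - tol && i + n > ei + ej)) {
      escore <- v
      ei <- i
      ej <- n
    }
  }
  # traceback (state priority M > X > Y)
  st <- "M"
  vv <- c(M[ei + 1, ej + 1], X[ei + 1, ej + 1], Y[ei + 1, ej + 1])
  st <- c("M", "X", "Y")[which.max(vv)]
  i <- ei
  j <- ej
  ra <- character(0)
  rb <- character(0)
  while (i > 0 && j > 0) {
    if (st == "M") {
      ra <- c(av[i], ra)
      rb <- c(bv[j], rb)
      need <- M[i + 1, j + 1] - sub[av[i], bv[j]]
      if (abs(M[i, j] - need) < tol) st <- "M"
      else if (abs(X[i, j] - need) < tol) st <- "X"
      else st <- "Y"
      i <- i - 1
      j <- j - 1
      if ((i == 0 || j == 0) && st == "M") break
    } else if (st == "X") {
      ra <- c(av[i], ra)
      rb <- c("-", rb)
      st <- if (abs(M[i, j + 1] - go - X[i + 1, j + 1]) < tol) "M" else "X"
      i <- i - 1
    } else {
      ra <- c("-", ra)
      rb <- c(bv[j], rb)
      st <- if (abs(M[i + 1, j] - go - Y[i + 1, j + 1]) < tol) "M" else "Y"
      j <- j - 1
    }
  }
  core <- ra != "-" & rb != "-"
  if (!any(core))
    return(list(score = escore, identity = 0, coverage_a = 0,
                coverage_b = 0))
  first <- which(core)[1]
  last <- max(which(core))
  seg <- seq(first, last)
  matches <- sum(ra[seg] == rb[seg] & ra[seg] != "-")
  list(score = escore,
       identity = matches / length(seg),
       coverage_a = sum(ra[seg] != "-") / m,
       coverage_b = sum(rb[seg] != "-") / n)
}

# greedy seed-recruitment clustering on precomputed oracle identities
oracle_greedy_cluster <- function(proteins, identity_min = 0.30,
                                  coverage_min = 0.70) {
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  n <- length(proteins)
  assigned <- logical(n)
  out <- list()
  for (i in seq_len(n)) {
    if (assigned[i]) next
    members <- i
    assigned[i] <- TRUE
    if (i < n) {
      for (j in seq(i + 1, n)) {
        if (assigned[j]) next
        r <- oracle_pairwise(proteins[[i]], proteins[[j]])
        if (r$identity >= identity_min && r$coverage_a >= coverage_min &&
            r$coverage_b >= coverage_min) {
          members <- c(members, j)
          assigned[j] <- TRUE
        }
      }
    }
    out[[length(out) + 1L]] <- sort(names(proteins)[members])
  }
  out
}

oracle_random_protein <- function(len) {
  paste(sample(ORACLE_AA, len, replace = TRUE), collapse = "")
}
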