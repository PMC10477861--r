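# Independent brute-force oracles used to validate the package's fast paths.
# These are deliberately naive implementations that share no code with the
# package internals.

# --- Benjamini-Hochberg step-up, straight from the definition -------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- ranked * n / seq_len(n)
  # enforce monotonicity from the largest rank down
  for (i in (n - 1):1) {
    if (n == 1) break
    adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# --- two-sided Wilcoxon rank-sum p by full enumeration of rank splits -----
# Enumerates all C(n1+n2, n1) assignments of the observed (tie-free) values
# to group 1 and counts splits with |W - E[W]| at least as extreme.
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 # Mann-Whitney U of group 1
  ew <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  w_all <- apply(combs, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

# --- affine-gap global alignment score by exhaustive recursion ------------
# Explores every global alignment as a monotone path with explicit gap
# state; gap of length L costs open + (L - 1) * ext. Exponential: only for
# sequences of length <= ~6.
oracle_affine_score <- function(a, b, sub, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  rec <- function(i, j, state) {
    # state: 0 none/diag, 1 gap consuming a, 2 gap consuming b
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1, j + 1, 0L))
    }
    if (i <= n) {
      cost <- if (state == 1L) ext else open
      best <- max(best, -cost + rec(i + 1, j, 1L))
    }
    if (j <= m) {
      cost <- if (state == 2L) ext else open
      best <- max(best, -cost + rec(i, j + 1, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# --- brute-force protein-space read mapping -----------------------------
# All-vs-all ungapped alignment of every translated fragment against every
# catalog peptide at every diagonal; best contiguous segment per diagonal by
# direct enumeration of all segments. Mirrors the mapper's acceptance rules
# but shares none of its search machinery.
oracle_map_read <- function(read, catalog, params, sub) {
  frags <- translate_six_frames(read, params$min_orf_len)$fragment
  best_score <- -Inf
  best_id <- NA_character_
  for (f in frags) {
    fv <- strsplit(f, "")[[1]]
    for (ri in seq_len(nrow(catalog$records))) {
      pep <- catalog$records$sequence[ri]
      pid <- catalog$records$id[ri]
      pv <- strsplit(pep, "")[[1]]
      for (diag in (-(length(fv) - 1)):(length(pv) - 1)) {
        q0 <- max(1, 1 - diag)
        q1 <- min(length(fv), length(pv) - diag)
        if (q1 - q0 + 1 < params$min_match_len) next
        qq <- q0:q1
        pos_scores <- sub[cbind(fv[qq], pv[qq + diag])]
        idents <- fv[qq] == pv[qq + diag]
        L <- length(pos_scores)
        # enumerate all contiguous segments via cumulative sums
        cs <- c(0, cumsum(pos_scores))
        ci <- c(0, cumsum(idents))
        for (s in 1:L) {
          e <- s:L
          span <- e - s + 1
          sc <- cs[e + 1] - cs[s]
          idn <- ci[e + 1] - ci[s]
          ok <- span >= params$min_match_len &
            idn >= params$min_identity * span - 1e-12
          if (!any(ok)) next
          sc_best <- max(sc[ok])
          if (sc_best > best_score ||
              (sc_best == best_score && !is.na(best_id) && pid < best_id)) {
            best_score <- sc_best
            best_id <- pid
          }
        }
      }
    }
  }
  best_id
}

# --- misc fixtures --------------------------------------------------------

random_peptides <- function(n, len_range = c(5, 12)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    l <- sample(seq(len_range[1], len_range[2]), 1)
    paste(sample(aa, l, replace = TRUE), collapse = "")
  }, character(1))
}

write_temp_fasta <- function(ids, seqs, width = 60) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  close(con)
  path
}

# log-normal null abundance matrix with both groups drawn from the same
# distribution
null_abundance_matrix <- function(n_pep, n_ctrl, n_case, meanlog = log(200),
                                  sdlog = 1) {
  vals <- matrix(rlnorm(n_pep * (n_ctrl + n_case), meanlog, sdlog),
                 nrow = n_pep)
  rownames(vals) <- sprintf("pep%04d", seq_len(n_pep))
  abundance_matrix(vals, c(rep("control", n_ctrl), rep("case", n_case)))
}
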