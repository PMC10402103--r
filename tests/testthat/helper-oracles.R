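# Independent oracles used across tests. Each reimplements the quantity it
# checks from first principles (grids, enumeration, closed forms), never by
# calling the code under test.

# Build a tiny marker_geno from a markers-x-individuals call matrix.
make_geno <- function(calls, scaffold = NULL, pos_bp = NULL,
                      chrom_class = "autosomal") {
  n_mar <- nrow(calls)
  markers <- tibble::tibble(
    marker_id = sprintf("m%02d", seq_len(n_mar)),
    scaffold = scaffold %||% rep("s1", n_mar),
    pos_bp = pos_bp %||% seq_len(n_mar) * 1000L,
    chrom_class = rep(chrom_class, length.out = n_mar)
  )
  marker_geno(markers, sprintf("i%02d", seq_len(ncol(calls))), calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-locus F2 likelihood on an explicit r grid (the rf estimator oracle).
rf_grid_oracle <- function(calls_A, calls_B, step = 1e-4) {
  ok <- !is.na(calls_A) & !is.na(calls_B)
  a <- match(calls_A[ok], c("AA", "AB", "BB"))
  b <- match(calls_B[ok], c("AA", "AB", "BB"))
  joint <- function(r) {
    hap <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
    hp <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
    T <- matrix(0, 3, 3)
    for (i in 1:4) for (j in 1:4) {
      ga <- hap[i, 1] + hap[j, 1] + 1
      gb <- hap[i, 2] + hap[j, 2] + 1
      T[ga, gb] <- T[ga, gb] + hp[i] * hp[j]
    }
    T
  }
  grid <- seq(0, 0.5, by = step)
  ll <- vapply(grid, function(r) {
    T <- joint(r)
    sum(log(T[cbind(a, b)]))
  }, numeric(1))
  best <- which.max(ll)
  list(r_hat = grid[best], lod = (ll[best] - ll[length(grid)]) / log(10))
}

# Brute-force F2 HMM posterior by enumerating all 3^M genotype paths.
hmm_enum_oracle <- function(obs, pos_cM, error_prob) {
  M <- length(obs)
  prior <- c(0.25, 0.5, 0.25)
  trans <- function(d) {
    r <- 0.5 * (1 - exp(-d / 50))
    matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
             r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
             r^2, 2 * r * (1 - r), (1 - r)^2), 3, 3, byrow = TRUE)
  }
  emit <- function(g, o) {
    if (is.na(o)) return(1)
    if (g == o) 1 - error_prob else error_prob / 2
  }
  paths <- as.matrix(expand.grid(rep(list(1:3), M)))
  w <- apply(paths, 1, function(p) {
    pr <- prior[p[1]] * emit(p[1], obs[1])
    for (k in seq_len(M - 1)) {
      T <- trans(pos_cM[k + 1] - pos_cM[k])
      pr <- pr * T[p[k], p[k + 1]] * emit(p[k + 1], obs[k + 1])
    }
    pr
  })
  post <- sapply(1:3, function(g) {
    vapply(seq_len(M), function(m) sum(w[paths[, m] == g]), numeric(1))
  })
  post / rowSums(post)
}

# Closed-form HK regression LOD at one fully typed marker via lm().
hk_lm_oracle <- function(calls, y) {
  a <- match(calls, c("AA", "AB", "BB")) - 2 # -1/0/1 dosage
  d <- as.numeric(calls == "AB")
  rss1 <- sum(resid(lm(y ~ a + d))^2)
  rss0 <- sum((y - mean(y))^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

# pFST grid oracle: maximize each group's likelihood over a 1e-4 frequency
# mesh and form the LRT.
pfst_grid_oracle <- function(pl_case, pl_bg, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  best_ll <- function(pl) {
    gl <- 10^(-pl / 10)
    max(vapply(grid, function(p) {
      sum(log(pmax(gl %*% c((1 - p)^2, 2 * p * (1 - p), p^2), 1e-300)))
    }, numeric(1)))
  }
  max(2 * (best_ll(pl_case) + best_ll(pl_bg) - best_ll(rbind(pl_case, pl_bg))), 0)
}

# Hard-call binomial LRT (the limit of pfst under certain genotypes).
hardcall_lrt_oracle <- function(gt_case, gt_bg) {
  ll <- function(gt, p) {
    hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    sum(log(pmax(hwe[gt + 1], 1e-300)))
  }
  mle <- function(gt) sum(gt) / (2 * length(gt))
  p1 <- mle(gt_case); p2 <- mle(gt_bg); p0 <- mle(c(gt_case, gt_bg))
  max(2 * (ll(gt_case, p1) + ll(gt_bg, p2) - ll(c(gt_case, gt_bg), p0)), 0)
}

# Truth-table oracle for the candidate-SNP rule at one site.
candidate_site_oracle <- function(gt_case, gt_bg, min_case_callrate = 0.8) {
  called <- !is.na(gt_case)
  fixed <- any(called) && all(gt_case[called] == 2L)
  rate_ok <- mean(called) >= min_case_callrate
  no_bg_hom <- !any(!is.na(gt_bg) & gt_bg == 2L)
  fixed && rate_ok && no_bg_hom
}

# Exhaustive per-offset/strand PWM rescoring oracle (independent of
# tfbs_scan's implementation details).
tfbs_rescore_oracle <- function(seq, p, core_cutoff, matrix_cutoff) {
  score_at <- function(codes, off, positions) {
    ci <- p$info[positions]
    f <- vapply(seq_along(positions), function(k) {
      b <- codes[off + positions[k] - 1]
      if (is.na(b)) 0 else p$freq[b, positions[k]]
    }, numeric(1))
    cur <- sum(ci * f)
    mn <- sum(ci * apply(p$freq[, positions, drop = FALSE], 2, min))
    mx <- sum(ci * apply(p$freq[, positions, drop = FALSE], 2, max))
    if (mx == mn) 1 else (cur - mn) / (mx - mn)
  }
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  L <- nchar(seq); w <- ncol(p$freq)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(seq) else rc(toupper(seq))
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    for (off in seq_len(L - w + 1)) {
      core <- score_at(codes, off, p$core)
      full <- score_at(codes, off, seq_len(w))
      if (core >= core_cutoff && full >= matrix_cutoff) {
        start0 <- if (strand == "+") off - 1L else L - (off - 1L) - w
        hits[[length(hits) + 1]] <- paste(p$id, start0, strand)
      }
    }
  }
  sort(unlist(hits))
}

# Windowed-identity brute force for one species' conserved bases (no
# boundary refinement; used to validate the raw window rule).
cne_window_oracle <- function(ref, sp, window = 100, min_identity = 0.70) {
  r <- strsplit(toupper(ref), "")[[1]]
  s <- strsplit(toupper(sp), "")[[1]]
  m <- s == r & s %in% c("A", "C", "G", "T")
  len <- length(m)
  qual <- logical(len)
  for (st in seq_len(len - window + 1)) {
    if (mean(m[st:(st + window - 1)]) > min_identity) {
      qual[st:(st + window - 1)] <- TRUE
    }
  }
  qual
}

# Random small PWM for oracle tests.
random_pwm <- function(id, width) {
  counts <- matrix(stats::rgamma(4 * width, 0.6), 4, width) * 20
  pwm(id, id, counts)
}
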