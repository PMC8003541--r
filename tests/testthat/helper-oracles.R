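# Independent oracles used across tests. These deliberately take the
# dumbest correct route (literal enumeration, quadratic scans, pairwise
# sums) so they share no code with the implementation they check.

# naive base-by-base reverse complement
rcOracle <- function(s, rna = TRUE) {
  comp <- if (rna) c(A = "U", C = "G", G = "C", U = "A", T = "A", N = "N")
          else c(A = "T", C = "G", G = "C", U = "A", T = "A", N = "N")
  ch <- strsplit(toupper(s), "")[[1]]
  paste(comp[rev(ch)], collapse = "")
}

# literal all-offset enumeration of the four canonical site patterns;
# returns data.frame(start, end, site_type) in 1-based closed coordinates
siteOracle <- function(mirnaSeq, utr) {
  utr <- chartr("T", "U", toupper(utr))
  seed <- substr(chartr("T", "U", toupper(mirnaSeq)), 2, 8)  # pos 2-8
  p6 <- rcOracle(substr(seed, 1, 6))          # rc of pos 2-7
  p7m8 <- rcOracle(seed)                      # rc of pos 2-8
  p7A1 <- paste0(p6, "A")
  p8 <- paste0(p7m8, "A")
  L <- nchar(utr)
  found <- list()
  scan <- function(pat, coreOffset, type) {
    k <- nchar(pat)
    if (L < k) return()
    for (i in seq_len(L - k + 1)) {
      if (substr(utr, i, i + k - 1) == pat)
        found[[length(found) + 1]] <<- data.frame(
          core = as.integer(i + coreOffset), start = as.integer(i),
          end = as.integer(i + k - 1), site_type = type)
    }
  }
  scan(p8, 1, "8mer"); scan(p7m8, 1, "7mer-m8")
  scan(p7A1, 0, "7mer-A1"); scan(p6, 0, "6mer")
  if (!length(found))
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0)))
  df <- do.call(rbind, found)
  prio <- c("8mer" = 4, "7mer-m8" = 3, "7mer-A1" = 2, "6mer" = 1)
  best <- do.call(rbind, lapply(split(df, df$core), function(d)
    d[which.max(prio[d$site_type]), ]))
  best <- best[order(best$core), c("start", "end", "site_type")]
  rownames(best) <- NULL
  best
}

# quadratic brute-force BH: q_i = min over j with p_(j) in the tail
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) m / j * p[o[j]])
    q[o[i]] <- min(1, vals)
  }
  q
}

# independent weighted log-rank statistic: vectorized risk-table route
wlrOracle <- function(time, event, g1, gehan = TRUE) {
  evT <- sort(unique(time[event == 1]))
  n <- outer(evT, time, function(t, x) x >= t)
  nj <- rowSums(n); n1j <- rowSums(n[, g1, drop = FALSE])
  dj <- sapply(evT, function(t) sum(time == t & event == 1))
  d1j <- sapply(evT, function(t) sum(time == t & event == 1 & g1))
  e1j <- dj * n1j / nj
  vj <- ifelse(nj > 1, dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1), 0)
  w <- if (gehan) nj else rep(1, length(nj))
  U <- sum(w * (d1j - e1j)); V <- sum(w^2 * vj)
  c(U = U, V = V, chi2 = if (V > 0) U^2 / V else 0)
}

# exact permutation p-value of the oracle statistic by complete enumeration
wlrExactOracle <- function(time, event, g1) {
  n <- length(time); n1 <- sum(g1)
  obs <- wlrOracle(time, event, g1)["chi2"]
  idx <- combn(n, n1)
  stats <- apply(idx, 2, function(ii) {
    m <- rep(FALSE, n); m[ii] <- TRUE
    wlrOracle(time, event, m)["chi2"]
  })
  mean(stats >= obs - 1e-12)
}

# pairwise Gehan generalized Wilcoxon statistic (no-censoring oracle)
gehanPairwise <- function(time, event, g1) {
  U <- 0
  for (i in which(g1)) for (j in which(!g1)) {
    # +1 if subject i definitely outlives j, -1 if definitely shorter
    if (time[i] > time[j] && event[j] == 1) U <- U + 1
    else if (time[i] < time[j] && event[i] == 1) U <- U - 1
  }
  U
}

randomUtr <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                        replace = TRUE), collapse = "")

# site GRanges -> plain ordered data.frame for oracle comparison
sitesToDf <- function(gr) {
  df <- data.frame(gene = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   site_type = as.character(S4Vectors::mcols(gr)$site_type))
  df[order(df$gene, df$start), ]
}
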