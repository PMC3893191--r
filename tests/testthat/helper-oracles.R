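# Independent oracles and small fixture builders shared across test files.
# Each oracle is a deliberately naive reimplementation kept separate from the
# package code paths it checks.

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# N50 as the largest length L such that contigs of length >= L together
# cover at least half the assembly (scan over candidate lengths)
oracle_n50 <- function(lens) {
  half <- sum(as.numeric(lens)) / 2
  cand <- sort(unique(lens), decreasing = TRUE)
  for (L in cand) if (sum(as.numeric(lens[lens >= L])) >= half) return(L)
  min(lens)
}

# reciprocal best hits by exhaustive enumeration over all id pairs
oracle_rbh <- function(hits_ab, hits_ba, cutoff = 1e-5) {
  best_of <- function(h, q) {
    rows <- h[h$query_id == q, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    rows <- rows[order(rows$evalue, -rows$bitscore, rows$subject_id), ,
                 drop = FALSE]
    rows[1, ]
  }
  pairs <- list()
  for (a in unique(hits_ab$query_id)) {
    ba <- best_of(hits_ab, a)
    if (is.null(ba) || ba$evalue > cutoff) next
    bb <- best_of(hits_ba, ba$subject_id)
    if (is.null(bb) || bb$evalue > cutoff) next
    if (bb$subject_id == a)
      pairs[[length(pairs) + 1]] <- c(a = a, b = ba$subject_id)
  }
  if (length(pairs) == 0)
    return(data.frame(id_a = character(0), id_b = character(0)))
  out <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(out) <- c("id_a", "id_b")
  out[order(out$id_a), , drop = FALSE]
}

# Needleman-Wunsch with match +1 / mismatch -1 / gap -1, tracking the
# maximum number of identities among maximum-score global alignments
oracle_nw <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)   # best score
  M <- matrix(0, n + 1, m + 1)   # most matches among best-score alignments
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eq <- A[i] == B[j]
      cand_s <- c(S[i, j] + ifelse(eq, 1, -1), S[i, j + 1] - 1, S[i + 1, j] - 1)
      cand_m <- c(M[i, j] + as.integer(eq), M[i, j + 1], M[i + 1, j])
      best <- max(cand_s)
      S[i + 1, j + 1] <- best
      M[i + 1, j + 1] <- max(cand_m[cand_s == best])
    }
  }
  list(score = S[n + 1, m + 1], matches = M[n + 1, m + 1])
}

# seed-and-extend intervals by direct scanning: for every diagonal of each
# strand, take seeds left to right (skipping those inside the previous
# extension on that diagonal) and extend ungapped with +1/-2 x-drop scoring
oracle_search_intervals <- function(query, subject, w = 11, x_drop = 20) {
  ext <- function(q, s, qi, sj) {
    # right
    score <- w; best_r <- 0; cur <- 0; len_r <- 0
    a <- qi + w; b <- sj + w
    while (a <= nchar(q) && b <= nchar(s)) {
      cur <- cur + ifelse(substr(q, a, a) == substr(s, b, b), 1, -2)
      if (cur > best_r) { best_r <- cur; len_r <- a - (qi + w) + 1 }
      if (best_r - cur >= x_drop) break
      a <- a + 1; b <- b + 1
    }
    best_l <- 0; cur <- 0; len_l <- 0
    a <- qi - 1; b <- sj - 1
    while (a >= 1 && b >= 1) {
      cur <- cur + ifelse(substr(q, a, a) == substr(s, b, b), 1, -2)
      if (cur > best_l) { best_l <- cur; len_l <- qi - a }
      if (best_l - cur >= x_drop) break
      a <- a - 1; b <- b - 1
    }
    c(q0 = qi - len_l, q1 = qi + w - 1 + len_r,
      s0 = sj - len_l, s1 = sj + w - 1 + len_r,
      score = w + best_l + best_r)
  }
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else holotome::revcomp(query)
    nq <- nchar(q); ns <- nchar(subject)
    if (nq < w) next
    for (d in (1 - nq):(ns - 1)) {       # diagonal = j - i
      covered <- 0
      i <- 1
      while (i + w - 1 <= nq) {
        j <- i + d
        if (j < 1 || j + w - 1 > ns) { i <- i + 1; next }
        if (i <= covered) { i <- i + 1; next }
        if (substr(q, i, i + w - 1) == substr(subject, j, j + w - 1)) {
          h <- ext(q, subject, i, j)
          covered <- h[["q1"]]
          if (strand == "+") {
            out[[length(out) + 1]] <- c(qs = h[["q0"]], qe = h[["q1"]],
                                        ss = h[["s0"]], se = h[["s1"]],
                                        score = h[["score"]])
          } else {
            out[[length(out) + 1]] <- c(qs = nq - h[["q1"]] + 1,
                                        qe = nq - h[["q0"]] + 1,
                                        ss = h[["s1"]], se = h[["s0"]],
                                        score = h[["score"]])
          }
          i <- covered + 1
        } else i <- i + 1
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(qs = integer(0), qe = integer(0), ss = integer(0),
                      se = integer(0), score = numeric(0)))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$qs, df$ss), , drop = FALSE]
}

# build a hit-table row in the standard 12-column layout
hit_row <- function(q, s, evalue, bitscore = 50, sstart = 1, send = 100) {
  data.frame(query_id = q, subject_id = s, pct_identity = 99, aln_len = 100,
             mismatches = 0, gap_opens = 0, qstart = 1, qend = 100,
             sstart = sstart, send = send, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}
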