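# Independent, loop-level transcriptions of the descriptor and metric
# formulas. Deliberately naive (per-term loops, no shared code with the
# package implementations) so they can serve as oracles.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

oracle_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(20)
  for (i in seq_along(AA20)) {
    n <- 0
    for (c in ch) if (c == AA20[i]) n <- n + 1
    out[i] <- n / length(ch)
  }
  out
}

oracle_dpc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(400)
  pos <- 0
  for (a in AA20) for (b in AA20) {
    pos <- pos + 1
    n <- 0
    for (i in seq_len(length(ch) - 1))
      if (ch[i] == a && ch[i + 1] == b) n <- n + 1
    out[pos] <- n / (length(ch) - 1)
  }
  out
}

oracle_ctdc <- function(seq, groupings) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(0)
  for (p in names(groupings)) {
    g <- groupings[[p]]
    for (grp in 1:3) {
      n <- 0
      for (c in ch) if (g[[c]] == grp) n <- n + 1
      out <- c(out, n / length(ch))
    }
  }
  out
}

oracle_apaac <- function(seq, lambda, w) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  p <- aa_properties()
  norm <- function(h) {
    mu <- mean(h)
    (h - mu) / sqrt(sum((h - mu)^2) / 20)
  }
  h1 <- stats::setNames(norm(p$hphob), rownames(p))
  h2 <- stats::setNames(norm(p$hphil), rownames(p))
  tau <- numeric(0)
  for (j in seq_len(lambda)) {
    t1 <- 0; t2 <- 0
    for (i in seq_len(n - j)) {
      t1 <- t1 + h1[[ch[i]]] * h1[[ch[i + j]]]
      t2 <- t2 + h2[[ch[i]]] * h2[[ch[i + j]]]
    }
    tau <- c(tau, t1 / (n - j), t2 / (n - j))
  }
  f <- numeric(20)
  for (i in seq_along(AA20)) f[i] <- sum(ch == AA20[i]) / n
  denom <- 1 + w * sum(tau)
  c(f / denom, w * tau / denom)
}

oracle_qsorder <- function(seq, nlag, w, d1, d2) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  f <- numeric(20)
  for (i in seq_along(AA20)) f[i] <- sum(ch == AA20[i]) / n
  taus <- function(dmat) {
    out <- numeric(nlag)
    for (d in seq_len(nlag)) {
      s <- 0
      for (i in seq_len(n - d)) s <- s + dmat[ch[i], ch[i + d]]^2
      out[d] <- s
    }
    out
  }
  t1 <- taus(d1); t2 <- taus(d2)
  c(f / (1 + w * sum(t1)), f / (1 + w * sum(t2)),
    w * t1 / (1 + w * sum(t1)), w * t2 / (1 + w * sum(t2)))
}

# pairwise-concordance (Mann-Whitney) AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
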