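# Independent reference implementations used to cross-check the pipeline.

# literal two-line transcription of the RMSSD definition
rmssd_oracle <- function(hp) {
  n <- length(hp)
  acc <- 0
  for (i in 2:n) acc <- acc + (hp[i] - hp[i - 1])^2
  sqrt(acc / (n - 1))
}

# brute-force local-mean detector: re-scans the whole series every
# iteration, finding neighbors by explicit search rather than vector shifts
karlsson_oracle <- function(hp, threshold, flagged_init = integer(0)) {
  n <- length(hp)
  flagged <- logical(n)
  flagged[flagged_init] <- TRUE
  repeat {
    snapshot <- flagged
    new <- integer(0)
    for (i in seq_len(n)) {
      if (snapshot[i]) next
      prev <- NA
      j <- i - 1
      while (j >= 1) {
        if (!snapshot[j]) { prev <- hp[j]; break }
        j <- j - 1
      }
      nxt <- NA
      j <- i + 1
      while (j <= n) {
        if (!snapshot[j]) { nxt <- hp[j]; break }
        j <- j + 1
      }
      neigh <- c(prev, nxt)
      neigh <- neigh[!is.na(neigh)]
      if (!length(neigh)) next
      L <- mean(neigh)
      if (abs(hp[i] - L) / L > threshold) new <- c(new, i)
    }
    if (!length(new)) break
    flagged[new] <- TRUE
  }
  flagged[flagged_init] <- FALSE
  which(flagged)
}

# a small complete item table with every instrument column set to `value`
constant_item_table <- function(n = 1, value = 0) {
  roster <- mh_item_roster()
  cols <- c(roster$mmapp, roster$ders, roster$dbis)
  d <- as.data.frame(matrix(value, nrow = n, ncol = length(cols)))
  names(d) <- cols
  d$participant_id <- sprintf("p%d", seq_len(n))
  d
}
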