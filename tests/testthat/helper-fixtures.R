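# Shared fixture builders and independent oracles.

# A minimal prompt table: `days` is a list of per-day binge vectors
# (0/1/NA); items are filled with simple deterministic values.
make_prompts <- function(days, interval = 2.5, first_clock = 8,
                         n_items = 3, id = "T1") {
  rows <- list()
  for (d in seq_along(days)) {
    b <- days[[d]]
    for (s in seq_along(b)) {
      ts <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC") +
        ((d - 1) * 24 + first_clock + (s - 1) * interval) * 3600
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = id, timestamp = ts, day = d, slot = s,
        answered = !is.na(b[s]),
        meal_type = dplyr::case_when(
          is.na(b[s]) ~ NA_character_,
          b[s] == 1 ~ "binge",
          TRUE ~ "main_meal"))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$cum_hours <- as.numeric(difftime(out$timestamp, out$timestamp[1],
                                       units = "hours"))
  for (j in seq_len(n_items)) {
    v <- seq_len(nrow(out)) * j %% 7 + j
    v[!out$answered] <- NA_real_
    out[[sprintf("item_%02d", j)]] <- v
  }
  out[, c("participant_id", "timestamp", "day", "slot", "cum_hours",
          "answered", sprintf("item_%02d", seq_len(n_items)), "meal_type")]
}

no_events <- function() {
  tibble::tibble(participant_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 excessive_amount = integer(), loss_of_control = integer())
}

make_dataset <- function(days, ...) {
  structure(list(prompts = make_prompts(days, ...), events = no_events(),
                 ground_truth = NULL),
            class = "ema_participant")
}

# O(n^2) pair-counting AUC oracle (ties counted half).
auc_brute <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden oracle: best J over every threshold placement,
# classifying positive at score >= cutoff.
youden_brute <- function(scores, y) {
  cands <- c(-Inf, sort(unique(scores)), Inf)
  best <- -Inf
  for (ct in cands) {
    sens <- sum(scores >= ct & y == 1) / sum(y == 1)
    spec <- sum(scores < ct & y == 0) / sum(y == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Independent top-k ranking oracle on complete data: plain correlation
# sort with stable tie-break by column position.
top_k_brute <- function(X, y, k) {
  r <- apply(X, 2, function(col) stats::cor(col, y))
  ord <- order(-abs(r))
  colnames(X)[ord[seq_len(k)]]
}
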