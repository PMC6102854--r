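# Shared fixture builders; everything is generated in code.

# A minimal arrayed study: one replicate, controls with exact medians.
tiny_study <- function(neg_median = 10, pos_median = 2,
                       lib = c(6, 4), replicate = "A_1", cell_line = "A",
                       plate = NULL) {
  df <- data.frame(
    feature_id = c(paste0("g", seq_along(lib)), "n1", "n2", "p1", "p2"),
    well_type = c(rep("library", length(lib)),
                  "neg_control", "neg_control", "pos_control", "pos_control"),
    cell_line = cell_line, replicate = replicate,
    readout = c(lib, neg_median, neg_median, pos_median, pos_median),
    stringsAsFactors = FALSE)
  if (!is.null(plate)) df$plate <- plate
  screen_study(df)
}

# A lethality_scores table built from per-replicate library vectors plus
# anchored controls (neg at 0, pos at 1 exactly).
scores_from_vectors <- function(..., n_ctrl = 2) {
  vecs <- list(...)
  reps <- names(vecs)
  stopifnot(!is.null(reps))
  blocks <- lapply(reps, function(r) {
    v <- vecs[[r]]
    data.frame(
      feature_id = c(sprintf("f%03d", seq_along(v)),
                     paste0("n", seq_len(n_ctrl)), paste0("p", seq_len(n_ctrl))),
      well_type = c(rep("library", length(v)),
                    rep("neg_control", n_ctrl), rep("pos_control", n_ctrl)),
      cell_line = sub("_.*", "", r), replicate = r,
      score = c(v, rep(0, n_ctrl), rep(1, n_ctrl)),
      stringsAsFactors = FALSE)
  })
  as_lethality_scores(do.call(rbind, blocks))
}

# Independent step-up oracle for the Benjamini-Hochberg adjustment.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted value of the i-th smallest: min over j >= i of p_(j) * m / j
    js <- seq(i, m)
    adj[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  adj
}
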