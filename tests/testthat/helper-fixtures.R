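# Fixtures are built in code; no binary data anywhere.

# Long score table for one tumor given a loss pattern matrix
# (logical foci x markers; TRUE = score 0, FALSE = score 2, NA = missing).
scores_from_pattern <- function(pattern, tumor_id = "T1", stage = "I") {
  foci <- rownames(pattern); mk <- colnames(pattern)
  data.frame(
    tumor_id = tumor_id, stage = stage,
    focus_id = rep(foci, times = length(mk)),
    marker = rep(mk, each = length(foci)),
    score = as.integer(ifelse(is.na(pattern), NA, ifelse(pattern, 0L, 2L))),
    stringsAsFactors = FALSE)
}

# The worked-example tumor: ARID1A & BRM lost in foci R1-R3,
# PBRM1 & BRG1 lost in R3 only, R4 evaluable and loss-free.
fig4a_pattern <- function() {
  m <- matrix(FALSE, 4, 5, dimnames = list(paste0("R", 1:4), ith_markers()))
  m[c("R1", "R2", "R3"), c("ARID1A", "BRM")] <- TRUE
  m["R3", c("PBRM1", "BRG1")] <- TRUE
  m
}

fig4a_cohort <- function() {
  as_cohort(scores_from_pattern(fig4a_pattern(), tumor_id = "SI_T05"))
}

# random loss pattern (no missing cells)
random_pattern <- function(n_foci, markers, p = 0.3) {
  matrix(stats::runif(n_foci * length(markers)) < p, n_foci, length(markers),
         dimnames = list(paste0("R", seq_len(n_foci)), markers))
}

# all set partitions of a character vector (Bell number; fine for n <= 5)
set_partitions <- function(x) {
  if (length(x) == 0L) return(list(list()))
  if (length(x) == 1L) return(list(list(x)))
  rest <- set_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p; q[[i]] <- c(x[1], q[[i]])
      out <- c(out, list(q))
    }
    out <- c(out, list(c(list(x[1]), p)))
  }
  out
}

# laminar check of a support list against a fixed family
compatible_with_family <- function(pieces, family) {
  all(vapply(pieces, function(p) {
    all(vapply(family, function(a) {
      pair_relation(p, a) != "conflict"
    }, logical(1)))
  }, logical(1)))
}
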