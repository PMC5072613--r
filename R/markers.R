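#' Default marker registry
#'
#' The five SWI/SNF-related chromatin regulators scored in the ccRCC tissue
#' microarray study, in the fixed order used for all deterministic
#' tie-breaking (event ordering, Newick labels, sibling order).
#'
#' @return Character vector of marker names.
#' @export
ith_markers <- function() {
  c("PBRM1", "ARID1A", "SETD2", "BRG1", "BRM")
}

ROMAN_STAGES <- c("I", "II", "III", "IV")

#' Convert tumor stage between Roman and ordinal encoding
#'
#' Stages are Roman numerals I--IV on input/output and ordinal integers 1--4
#' internally.
#'
#' @param x Vector of stages, Roman (character) or ordinal (numeric).
#' @return `stage_to_int()` returns an integer vector in 1..4;
#'   `stage_to_roman()` returns a character vector in I..IV.
#' @export
stage_to_int <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(x)
  } else {
    out <- match(toupper(trimws(as.character(x))), ROMAN_STAGES)
    # tolerate "1".."4" spelled as digits
    digit <- is.na(out) & grepl("^[1-4]$", trimws(as.character(x)))
    out[digit] <- as.integer(trimws(as.character(x))[digit])
  }
  if (any(!is.na(out) & !(out %in% 1:4))) {
    stop("stage must be I, II, III or IV (or 1-4)")
  }
  out
}

#' @rdname stage_to_int
#' @export
stage_to_roman <- function(x) {
  ROMAN_STAGES[stage_to_int(x)]
}
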