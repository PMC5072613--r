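#' Construct a validated IHC cohort from a long score table
#'
#' The canonical representation is long format: one row per
#' (tumor, focus, marker) carrying an ordinal score in \{0,1,2\} and/or a
#' fraction of positively stained tumor cells in \[0,1\]. Missing cells are
#' non-evaluable; they are never imputed as positive or as lost.
#'
#' @param scores data.frame with columns `tumor_id`, `stage`, `focus_id`,
#'   `marker` and at least one of `score`, `fraction_positive`.
#' @param markers Ordered marker registry; rows with markers outside the
#'   registry are rejected (reported in the `rejected` attribute), not an
#'   error.
#' @param provenance Free-text metadata recorded on the object.
#' @return An object of class `ihc_cohort`: a list with elements `scores`
#'   (validated long table with an `evaluable` column), `markers`, and
#'   `provenance`. Attribute `rejected` holds a per-row report of any
#'   unknown-marker rows.
#' @export
as_cohort <- function(scores, markers = ith_markers(), provenance = "") {
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  if (nrow(scores) == 0L) stop("no records")
  required <- c("tumor_id", "stage", "focus_id", "marker")
  missing_cols <- setdiff(required, names(scores))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!("score" %in% names(scores)) && !("fraction_positive" %in% names(scores))) {
    stop("need at least one of 'score', 'fraction_positive'")
  }
  if (!("score" %in% names(scores))) scores$score <- NA_integer_
  if (!("fraction_positive" %in% names(scores))) scores$fraction_positive <- NA_real_

  scores$tumor_id <- as.character(scores$tumor_id)
  scores$focus_id <- as.character(scores$focus_id)
  scores$marker <- as.character(scores$marker)
  scores$stage <- stage_to_int(scores$stage)
  if (anyNA(scores$stage)) stop("stage missing or unparseable for some rows")

  # unknown markers: rejected with a per-row report, validation stays total
  unknown <- !(scores$marker %in% markers)
  rejected <- scores[unknown, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- "unknown marker"
    warning(sprintf("%d row(s) with unknown marker rejected (see attr 'rejected')",
                    nrow(rejected)))
  }
  scores <- scores[!unknown, , drop = FALSE]
  if (nrow(scores) == 0L) stop("no records")

  sc <- suppressWarnings(as.numeric(scores$score))
  bad_score <- !is.na(sc) & !(sc %in% 0:2)
  if (any(bad_score)) {
    stop("score outside {0,1,2} for key(s): ",
         paste(utils::head(key_of(scores[bad_score, ]), 5L), collapse = "; "))
  }
  scores$score <- as.integer(sc)
  fp <- suppressWarnings(as.numeric(scores$fraction_positive))
  if (any(!is.na(fp) & (fp < 0 | fp > 1))) {
    stop("fraction_positive outside [0,1]")
  }
  scores$fraction_positive <- fp

  keys <- key_of(scores)
  dup <- duplicated(keys)
  if (any(dup)) {
    stop("duplicate (tumor, focus, marker) record(s): ",
         paste(unique(keys[dup]), collapse = "; "))
  }

  # a tumor's foci must all carry the tumor's stage
  st <- tapply(scores$stage, scores$tumor_id, function(s) length(unique(s)))
  if (any(st > 1L)) {
    stop("inconsistent stage within tumor(s): ",
         paste(names(st)[st > 1L], collapse = ", "))
  }

  scores$evaluable <- !is.na(scores$score) | !is.na(scores$fraction_positive)

  nf <- tapply(scores$focus_id, scores$tumor_id, function(f) length(unique(f)))
  if (any(nf < 2L)) {
    warning("tumor(s) with fewer than 2 foci retained: ",
            paste(names(nf)[nf < 2L], collapse = ", "))
  }

  ord <- order(scores$tumor_id, scores$focus_id, match(scores$marker, markers))
  scores <- scores[ord, c("tumor_id", "stage", "focus_id", "marker",
                          "score", "fraction_positive", "evaluable")]
  rownames(scores) <- NULL

  out <- structure(
    list(scores = scores, markers = markers, provenance = provenance),
    class = "ihc_cohort"
  )
  attr(out, "rejected") <- rejected
  out
}

key_of <- function(df) {
  paste0("(", df$tumor_id, ", ", df$focus_id, ", ", df$marker, ")")
}

#' @export
print.ihc_cohort <- function(x, ...) {
  s <- x$scores
  cat(sprintf("ihc_cohort: %d tumors, %d foci, %d markers, %d records\n",
              length(unique(s$tumor_id)),
              nrow(unique(s[, c("tumor_id", "focus_id")])),
              length(x$markers), nrow(s)))
  tab <- table(factor(stage_to_roman(tapply(s$stage, s$tumor_id, `[`, 1L)),
                      levels = ROMAN_STAGES))
  cat("tumors per stage:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of tumors in a cohort
#' @param cohort An `ihc_cohort`.
#' @return Integer.
#' @export
n_tumors <- function(cohort) length(unique(cohort$scores$tumor_id))

#' Per-tumor stage lookup
#' @param cohort An `ihc_cohort`.
#' @return Named integer vector (ordinal stage), one entry per tumor.
#' @export
tumor_stages <- function(cohort) {
  s <- cohort$scores
  vapply(split(s$stage, s$tumor_id), `[`, integer(1), 1L)
}

#' Read a focus-level IHC score table
#'
#' Supported dialects:
#' \describe{
#'   \item{`long-csv`}{one row per (tumor, focus, marker); columns
#'     `tumor_id`, `stage`, `focus_id`, `marker`, and `score` and/or
#'     `fraction_positive`.}
#'   \item{`wide-csv`}{one row per (tumor, focus); columns `tumor_id`,
#'     `stage`, `focus_id`, then one score column per marker.}
#'   \item{`s1-xls`}{the study's supplementary score workbook; read with a
#'     permissive header map (case-insensitive matching of tumor/case,
#'     stage, focus columns and marker names) and reshaped to long format.
#'     Requires the `readxl` package.}
#' }
#' Empty cells become non-evaluable. Header matching is case-insensitive.
#'
#' @param path File path.
#' @param dialect One of `"long-csv"`, `"wide-csv"`, `"s1-xls"`.
#' @param markers Marker registry passed to [as_cohort()].
#' @return A validated [as_cohort()] object.
#' @export
read_cohort <- function(path, dialect = c("long-csv", "wide-csv", "s1-xls"),
                        markers = ith_markers()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "s1-xls") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading the XLS dialect requires the 'readxl' package")
    }
    df <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (nrow(df) == 0L) stop("no records")
  names(df) <- map_headers(names(df), markers)
  long <- if (dialect == "long-csv") df else wide_to_long(df, markers)
  as_cohort(long, markers = markers, provenance = paste0(dialect, ":", path))
}

# case-insensitive permissive header map: tumor/case -> tumor_id, etc.
map_headers <- function(nms, markers) {
  low <- tolower(trimws(nms))
  canon <- function(patterns, to) {
    hit <- which(low %in% patterns | grepl(paste(patterns, collapse = "|"), low))
    if (length(hit)) nms[hit[1]] <<- to
  }
  canon(c("^tumor_?id$", "^tumou?r$", "^case_?i?d?$", "^patient"), "tumor_id")
  canon(c("^stage$", "^tumor_?stage$"), "stage")
  canon(c("^focus_?id$", "^focus$", "^core$", "^region$"), "focus_id")
  canon(c("^marker$", "^protein$", "^antibody$"), "marker")
  canon(c("^score$", "^ihc_?score$"), "score")
  canon(c("^fraction_?positive$", "^fraction$", "^percent_?positive$"),
        "fraction_positive")
  # marker columns matched case-insensitively
  m <- match(low, tolower(markers))
  nms[!is.na(m)] <- markers[m[!is.na(m)]]
  nms
}

wide_to_long <- function(df, markers) {
  present <- intersect(markers, names(df))
  if (!length(present)) stop("no marker columns found in wide table")
  id_cols <- intersect(c("tumor_id", "stage", "focus_id"), names(df))
  out <- do.call(rbind, lapply(present, function(m) {
    cbind(df[, id_cols, drop = FALSE],
          data.frame(marker = m, score = df[[m]], stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' Write result tables to a directory
#'
#' Deterministic file names derived from the (named) list of tables:
#' data.frames become CSV with their column order preserved, clone trees and
#' newick strings become `.nwk`, other lists become JSON. A manifest listing
#' every file with its row count is written as `manifest.json` and returned.
#'
#' @param tables Named list of result objects.
#' @param out_dir Output directory, created if needed.
#' @return data.frame manifest (file, rows), invisibly also written to disk.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L) stop("output directory not writable: ", out_dir)
  if (length(tables) && is.null(names(tables))) stop("tables must be named")
  files <- character(0); rows <- integer(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE)
      files <- c(files, basename(f)); rows <- c(rows, nrow(x))
    } else if (inherits(x, "clone_tree")) {
      f <- file.path(out_dir, paste0(nm, ".nwk"))
      writeLines(to_newick(x), f)
      files <- c(files, basename(f)); rows <- c(rows, 1L)
    } else if (is.character(x) && length(x) >= 1L && all(grepl(";\\s*$", x))) {
      f <- file.path(out_dir, paste0(nm, ".nwk"))
      writeLines(x, f)
      files <- c(files, basename(f)); rows <- c(rows, length(x))
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
      files <- c(files, basename(f)); rows <- c(rows, length(x))
    }
  }
  manifest <- data.frame(file = files, rows = rows, stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
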