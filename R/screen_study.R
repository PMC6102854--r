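#' Construct a screen study
#'
#' A `screen_study` is a long-format table of arrayed- or pooled-screen
#' measurements: one row per well (arrayed) or per guide-by-sample cell
#' (pooled). It is the common entry point for all normalization methods in
#' the package.
#'
#' @param x A data frame with columns `feature_id`, `well_type`,
#'   `cell_line`, `replicate`, `readout` and optionally `plate`. `well_type`
#'   must contain values in `c("library", "neg_control", "pos_control")`.
#'   Additional columns are retained untouched as annotations.
#'
#' @details
#' Validation enforces the structural invariants every downstream step
#' relies on:
#' * every replicate carries at least one negative and one positive control;
#' * all readouts are finite;
#' * a replicate belongs to exactly one cell line;
#' * plate annotation is all-or-nothing within a replicate.
#'
#' Rows with missing readout are dropped with a message (never imputed).
#'
#' @return The validated data frame with class `screen_study`.
#' @examples
#' df <- data.frame(
#'   feature_id = c("g1", "g2", "nc", "pc"),
#'   well_type  = c("library", "library", "neg_control", "pos_control"),
#'   cell_line  = "A", replicate = "A_1",
#'   readout    = c(1.2, 0.4, 1.0, 0.1)
#' )
#' screen_study(df)
#' @export
screen_study <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("feature_id", "well_type", "cell_line", "replicate", "readout")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$feature_id <- as.character(x$feature_id)
  x$well_type <- as.character(x$well_type)
  x$cell_line <- as.character(x$cell_line)
  x$replicate <- as.character(x$replicate)
  bad_type <- setdiff(unique(x$well_type), WELL_TYPES)
  if (length(bad_type)) {
    stop("unknown well_type value(s): ", paste(bad_type, collapse = ", "),
         " (expected ", paste(WELL_TYPES, collapse = "/"), ")")
  }
  if (!is.numeric(x$readout)) stop("readout must be numeric")

  n_na <- sum(is.na(x$readout))
  if (n_na > 0) {
    message("dropping ", n_na, " row(s) with missing readout")
    x <- x[!is.na(x$readout), , drop = FALSE]
  }
  if (any(!is.finite(x$readout))) {
    stop("non-finite readout value(s) at row(s): ",
         paste(utils::head(which(!is.finite(x$readout)), 5), collapse = ", "))
  }

  validate_study_structure(x)
  class(x) <- c("screen_study", "data.frame")
  x
}

WELL_TYPES <- c("library", "neg_control", "pos_control")

validate_study_structure <- function(x) {
  # replicate -> single cell line
  map <- unique(x[, c("replicate", "cell_line")])
  dup <- map$replicate[duplicated(map$replicate)]
  if (length(dup)) {
    stop("replicate(s) assigned to more than one cell line: ",
         paste(unique(dup), collapse = ", "))
  }
  # controls present per replicate
  for (ct in c("neg_control", "pos_control")) {
    has <- tapply(x$well_type == ct, x$replicate, any)
    if (any(!has)) {
      stop("replicate(s) without ", ct, " wells: ",
           paste(names(has)[!has], collapse = ", "))
    }
  }
  # plate annotation all-or-nothing within replicate
  if ("plate" %in% names(x)) {
    part <- tapply(is.na(x$plate), x$replicate, function(z) any(z) && !all(z))
    if (any(part)) {
      stop("replicate(s) with plate annotation on only some rows: ",
           paste(names(part)[part], collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.screen_study <- function(x, ...) {
  cat("screen_study: ", nrow(x), " records, ",
      length(unique(x$replicate)), " replicate(s), ",
      length(unique(x$cell_line)), " cell line(s)\n", sep = "")
  tab <- table(x$well_type)
  cat("  well types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if ("plate" %in% names(x) && !all(is.na(x$plate))) {
    cat("  plates:", length(unique(stats::na.omit(x$plate))), "\n")
  }
  invisible(x)
}

#' Read an arrayed screen table
#'
#' Reads a delimited long-format file (one row per well) into a
#' [screen_study()]. Column names and well-type labels in the file are mapped
#' onto the package's canonical names, so files produced by different plate
#' readers or LIMS exports can be ingested without editing.
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @param column_map Named character vector mapping canonical names
#'   (`feature_id`, `well_type`, `cell_line`, `replicate`, `plate`, `readout`)
#'   to the column names used in the file. Defaults to the identity mapping.
#' @param well_type_map Named character vector mapping file values to the
#'   canonical well types. Default accepts `lib`/`neg`/`pos` and the canonical
#'   names themselves.
#' @param sep Field separator; `NULL` (default) guesses from the file
#'   extension (`.csv` is comma, anything else tab).
#' @return A [screen_study()]; row order of the file is preserved, and
#'   unmapped columns are kept as annotations.
#' @export
read_arrayed_table <- function(path, column_map = NULL, well_type_map = NULL,
                               sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  canonical <- c("feature_id", "well_type", "cell_line", "replicate",
                 "plate", "readout")
  cm <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) cm[names(column_map)] <- column_map
  for (canon in canonical) {
    src <- cm[[canon]]
    if (src %in% names(raw) && src != canon) {
      names(raw)[names(raw) == src] <- canon
    }
  }
  required <- setdiff(canonical, "plate")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  wtm <- c(lib = "library", neg = "neg_control", pos = "pos_control",
           stats::setNames(WELL_TYPES, WELL_TYPES))
  if (!is.null(well_type_map)) wtm <- c(well_type_map, wtm)
  unknown <- setdiff(unique(raw$well_type), names(wtm))
  if (length(unknown)) {
    stop("unmappable well_type value(s): ", paste(unknown, collapse = ", "))
  }
  raw$well_type <- unname(wtm[raw$well_type])
  if (!is.numeric(raw$readout)) {
    suppressWarnings(num <- as.numeric(raw$readout))
    bad <- which(is.na(num) & !is.na(raw$readout) & raw$readout != "")
    if (length(bad)) {
      stop("non-numeric readout at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    raw$readout <- num
  }
  screen_study(raw)
}

#' Read a pooled-screen count matrix
#'
#' Reads a guide-level count table in the common pooled-screen layout
#' (tab-separated; columns `sgRNA`, `gene`, then one column per sample) and
#' converts it to a long-format [screen_study()] with counts as readouts.
#'
#' @param path Path to the tab-separated count file.
#' @param controls Either a path to a two-column file (guide id, label
#'   `neg`/`pos`) or a named character vector `c(guide = "neg", ...)` marking
#'   control guides. Required: a screen without assay controls cannot be
#'   anchored.
#' @param sample_map Either `NULL`, in which case sample column names must
#'   follow the `cellline_replicate` convention (last underscore splits), or
#'   a data frame with columns `sample`, `cell_line`, `replicate`.
#' @return A [screen_study()] with one record per guide and sample; guides
#'   listed in `controls` are labelled `neg_control`/`pos_control`, all
#'   others `library`.
#' @export
read_count_matrix <- function(path, controls, sample_map = NULL) {
  counts <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(counts) < 3) stop("count table needs sgRNA, gene and >=1 sample column")
  guide_col <- names(counts)[1]
  dup <- counts[[guide_col]][duplicated(counts[[guide_col]])]
  if (length(dup)) stop("duplicate guide id(s): ", paste(unique(dup), collapse = ", "))

  samples <- names(counts)[-(1:2)]
  if (is.null(sample_map)) {
    m <- regmatches(samples, regexpr("_[^_]+$", samples))
    if (length(m) != length(samples)) {
      stop("sample column(s) not in 'cellline_replicate' form; supply sample_map")
    }
    sample_map <- data.frame(sample = samples,
                             cell_line = sub("_[^_]+$", "", samples),
                             replicate = samples,
                             stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("sample", "cell_line", "replicate") %in% names(sample_map)))
    missing_s <- setdiff(samples, sample_map$sample)
    if (length(missing_s)) {
      stop("sample(s) absent from sample_map: ", paste(missing_s, collapse = ", "))
    }
  }

  if (missing(controls) || is.null(controls)) {
    stop("a control list is required: pooled counts carry no well annotation")
  }
  if (is.character(controls) && length(controls) == 1 && file.exists(controls)) {
    cl <- utils::read.table(controls, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    controls <- stats::setNames(cl[[2]], cl[[1]])
  }
  if (!all(controls %in% c("neg", "pos"))) {
    stop("control labels must be 'neg' or 'pos'")
  }

  for (s in samples) {
    v <- counts[[s]]
    if (!is.numeric(v)) stop("non-numeric counts in sample ", s)
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative count for guide ", counts[[guide_col]][which(v < 0)[1]],
           " in sample ", s)
    }
  }

  wt <- rep("library", nrow(counts))
  idx <- match(counts[[guide_col]], names(controls))
  wt[!is.na(idx)] <- ifelse(controls[idx[!is.na(idx)]] == "neg",
                            "neg_control", "pos_control")

  long <- do.call(rbind, lapply(samples, function(s) {
    i <- match(s, sample_map$sample)
    data.frame(feature_id = counts[[guide_col]],
               gene = counts[[2]],
               well_type = wt,
               cell_line = sample_map$cell_line[i],
               replicate = sample_map$replicate[i],
               readout = as.numeric(counts[[s]]),
               stringsAsFactors = FALSE)
  }))
  screen_study(long)
}

#' Transform readouts
#'
#' Applies an elementwise variance-stabilizing or orienting transform to the
#' readouts of a study. Counts from pooled screens are typically `log2`
#' (with a pseudocount) or `asinh` transformed before scoring; `negate` flips
#' orientation so that lower values mean more lethality.
#'
#' @param study A [screen_study()].
#' @param kind One of `"identity"`, `"log2"`, `"asinh"`, `"negate"`.
#' @param pseudocount Non-negative value added before `log2`; required to be
#'   large enough that all shifted readouts are positive.
#' @return The study with readouts replaced; all annotations untouched.
#' @export
transform_readout <- function(study,
                              kind = c("identity", "log2", "asinh", "negate"),
                              pseudocount = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(study, "screen_study"), pseudocount >= 0)
  x <- study$readout
  study$readout <- switch(kind,
    identity = x,
    log2 = {
      if (any(x + pseudocount <= 0)) {
        stop("log2 of non-positive value; increase pseudocount (current ",
             pseudocount, ")")
      }
      log2(x + pseudocount)
    },
    asinh = asinh(x),
    negate = -x
  )
  study
}

#' Check assay-control adequacy
#'
#' Report-only sanity check of control counts against practical minima:
#' pooled replicates want roughly 20 of each control type to estimate the
#' functional range stably; arrayed plates can be corrected reliably with 4
#' of each type per plate, with an absolute minimum of 2. Positive-control
#' sets with zero variability (e.g. all zero reads after depletion) are
#' flagged, since they degenerate the functional range.
#'
#' @param study A [screen_study()].
#' @param design `"arrayed"` (checked per plate if plates are annotated,
#'   else per replicate) or `"pooled"` (checked per replicate).
#' @return A data frame of class `control_report` with one row per checked
#'   scope and control type: counts, a `level` of `"ok"`, `"warning"` or
#'   `"error"`, and a message. The study is never modified.
#' @export
validate_controls <- function(study, design = c("arrayed", "pooled")) {
  design <- match.arg(design)
  stopifnot(inherits(study, "screen_study"))
  per_plate <- design == "arrayed" && "plate" %in% names(study) &&
    !all(is.na(study$plate))
  scope <- if (per_plate) paste(study$replicate, study$plate, sep = "/")
           else study$replicate
  rows <- list()
  for (sc in unique(scope)) {
    sub <- study[scope == sc, , drop = FALSE]
    for (ct in c("neg_control", "pos_control")) {
      v <- sub$readout[sub$well_type == ct]
      n <- length(v)
      min_warn <- if (design == "pooled") 20L else 4L
      level <- "ok"; msg <- ""
      if (design == "arrayed" && n < 2) {
        level <- "error"; msg <- "below absolute minimum of 2 per plate"
      } else if (n < min_warn) {
        level <- "warning"
        msg <- paste0("fewer than ", min_warn, " controls")
      }
      zero_var <- n >= 2 && stats::var(v) == 0
      if (zero_var && level == "ok") {
        level <- "warning"; msg <- "zero variability among controls"
      } else if (zero_var) {
        msg <- paste0(msg, "; zero variability among controls")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scope = sc, well_type = ct, n = n, zero_variability = zero_var,
        level = level, message = msg, stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("control_report", "data.frame")
  rep
}

#' @export
print.control_report <- function(x, ...) {
  n_err <- sum(x$level == "error"); n_warn <- sum(x$level == "warning")
  cat("control_report: ", nrow(x), " checks, ", n_err, " error(s), ",
      n_warn, " warning(s)\n", sep = "")
  bad <- x[x$level != "ok", , drop = FALSE]
  if (nrow(bad)) print.data.frame(bad, row.names = FALSE)
  invisible(x)
}

#' Filter unreliable positive controls
#'
#' Pooled-screen libraries often include candidate positive controls that do
#' not actually deplete in every replicate. Controls that fail to show a
#' lethal phenotype in enough replicates are demoted to ordinary library
#' features so they cannot distort the functional range.
#'
#' A control is counted as "lethal in replicate k" when its readout lies
#' beyond the `lethal_rule` quantile of that replicate's library readouts,
#' in the direction given by `lethal_direction` (`"low"` for count/viability
#' data where depletion lowers the readout; `"high"` for readouts oriented
#' the other way).
#'
#' @param study A [screen_study()] (readouts already on the scale used for
#'   scoring, i.e. after [transform_readout()]).
#' @param min_lethal_replicates Minimum number of replicates in which a
#'   positive control must look lethal to be retained.
#' @param lethal_rule Quantile of library readouts defining "lethal";
#'   in (0, 1), default 0.10.
#' @param lethal_direction `"low"` or `"high"`.
#' @return The study with failing positive controls relabelled `library`.
#'   An attribute `"demoted"` lists the relabelled feature ids.
#' @export
filter_reference_controls <- function(study, min_lethal_replicates,
                                      lethal_rule = 0.10,
                                      lethal_direction = c("low", "high")) {
  lethal_direction <- match.arg(lethal_direction)
  stopifnot(inherits(study, "screen_study"),
            lethal_rule > 0, lethal_rule < 1)
  pos_ids <- unique(study$feature_id[study$well_type == "pos_control"])
  reps <- unique(study$replicate)
  thr <- vapply(reps, function(r) {
    lib <- study$readout[study$replicate == r & study$well_type == "library"]
    p <- if (lethal_direction == "low") lethal_rule else 1 - lethal_rule
    stats::quantile(lib, p, type = 7, names = FALSE)
  }, numeric(1))
  names(thr) <- reps

  n_lethal <- vapply(pos_ids, function(id) {
    sub <- study[study$feature_id == id & study$well_type == "pos_control", ]
    ok <- if (lethal_direction == "low") sub$readout <= thr[sub$replicate]
          else sub$readout >= thr[sub$replicate]
    length(unique(sub$replicate[ok]))
  }, integer(1))

  demote <- pos_ids[n_lethal < min_lethal_replicates]
  if (length(demote) == length(pos_ids)) {
    stop("all candidate positive controls filtered out; none meet the ",
         "lethal-phenotype rule in >= ", min_lethal_replicates, " replicates")
  }
  sel <- study$well_type == "pos_control" & study$feature_id %in% demote
  study$well_type[sel] <- "library"
  attr(study, "demoted") <- demote
  study
}
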