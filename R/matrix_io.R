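# Whole-brain connectivity matrices: constructors, plain-text I/O, and
# cohort directories (manifest + one dense text matrix per subject per
# modality).

#' Construct a whole-brain connectivity matrix
#'
#' Validates and wraps a square symmetric weight matrix. The diagonal is
#' forced to zero (self-connections are excluded from every summary);
#' functional weights must lie in \[-1, 1\], structural weights must be
#' non-negative.
#'
#' @param weights square numeric matrix.
#' @param subject_id subject identifier.
#' @param modality "functional" or "structural".
#' @param sym_tol largest tolerated absolute asymmetry; within tolerance the
#'   matrix is symmetrized as `(W + t(W))/2`.
#' @return object of class `wholebrain_matrix` (list: subject_id, modality,
#'   weights).
#' @export
wholebrain_matrix <- function(weights, subject_id = "subject",
                              modality = c("functional", "structural"),
                              sym_tol = 1e-6) {
  modality <- match.arg(modality)
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop("weights must be a square matrix")
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > sym_tol) {
    stop("matrix is asymmetric beyond tolerance (max |W - t(W)| = ",
         format(asym), ")")
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    message("nonzero diagonal entries set to zero (self-connections excluded)")
    diag(weights) <- 0
  }
  if (modality == "functional") {
    if (any(weights < -1 | weights > 1)) {
      stop("functional weights must lie in [-1, 1]")
    }
  } else if (any(weights < 0)) {
    stop("structural weights must be non-negative")
  }
  structure(list(subject_id = subject_id, modality = modality,
                 weights = weights),
            class = "wholebrain_matrix")
}

#' Read a whole-brain matrix from a dense text file
#'
#' Reads a whitespace- or comma-delimited square matrix with no header and
#' validates it via [wholebrain_matrix()].
#'
#' @param path file path.
#' @param modality "functional" or "structural".
#' @param subject_id subject identifier to attach.
#' @param sep field separator; `NULL` auto-detects comma vs whitespace.
#' @param sym_tol asymmetry tolerance.
#' @return a `wholebrain_matrix`.
#' @export
read_matrix <- function(path, modality = c("functional", "structural"),
                        subject_id = NULL, sep = NULL, sym_tol = 1e-6) {
  modality <- match.arg(modality)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  }
  df <- utils::read.table(path, header = FALSE, sep = sep)
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    stop("matrix file is not square: ", nrow(m), " x ", ncol(m))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  wholebrain_matrix(m, subject_id = subject_id, modality = modality,
                    sym_tol = sym_tol)
}

#' Write a whole-brain matrix as dense text
#'
#' @param m a `wholebrain_matrix` or plain matrix.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return invisibly, the path.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  w <- if (inherits(m, "wholebrain_matrix")) m$weights else m
  txt <- apply(w, 1, function(row) paste(sprintf("%.17g", row), collapse = sep))
  writeLines(txt, path)
  invisible(path)
}

#' Read a subject table
#'
#' Delimited table with columns `subject_id`, `group` (MDD/HC), `age`,
#' `gender`, `education`, `mean_fd`, `hamd`, `duration`. Checks id
#' uniqueness, non-negative head motion, and (optionally) the inclusion rule
#' HAMD >= 18 for MDD rows.
#'
#' @param path file path.
#' @param check_hamd enforce HAMD >= 18 for the MDD group.
#' @return data.frame of class `subject_table`.
#' @export
read_subjects <- function(path, check_hamd = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_subjects(df, check_hamd = check_hamd)
}

#' Validate a subject table
#' @param df data.frame with the subject columns.
#' @param check_hamd enforce HAMD >= 18 for MDD rows.
#' @return validated data.frame classed `subject_table`.
#' @export
validate_subjects <- function(df, check_hamd = FALSE) {
  need <- c("subject_id", "group", "age", "gender", "education", "mean_fd",
            "hamd", "duration")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("subject table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) stop("subject_id values must be unique")
  if (!all(df$group %in% c("MDD", "HC"))) stop("group must be 'MDD' or 'HC'")
  if (any(df$mean_fd < 0)) stop("mean_fd must be non-negative")
  if (any(df$hamd < 0)) stop("hamd must be non-negative")
  if (check_hamd && any(df$group == "MDD" & df$hamd < 18)) {
    stop("MDD rows must have HAMD >= 18 (inclusion rule)")
  }
  class(df) <- c("subject_table", "data.frame")
  df
}

#' Write a cohort directory
#'
#' Writes subjects.tsv, one dense text matrix per subject and modality, and a
#' manifest.tsv mapping subject ids to matrix files. If ground truth from the
#' synthetic generator is supplied it is stored as ground_truth.json.
#'
#' @param cohort a `connectome_cohort` (see [generate_cohort()]).
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(cohort$subjects, file.path(dir, "subjects.tsv"))
  man <- data.frame(subject_id = character(0), functional = character(0),
                    structural = character(0), stringsAsFactors = FALSE)
  for (id in cohort$subjects$subject_id) {
    fp <- paste0(id, "_functional.txt")
    sp <- paste0(id, "_structural.txt")
    write_matrix(cohort$matrices[[id]]$functional, file.path(dir, fp))
    write_matrix(cohort$matrices[[id]]$structural, file.path(dir, sp))
    man <- rbind(man, data.frame(subject_id = id, functional = fp,
                                 structural = sp, stringsAsFactors = FALSE))
  }
  write_table(man, file.path(dir, "manifest.tsv"))
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir directory written by [write_cohort()] (manifest.tsv,
#'   subjects.tsv, matrix files).
#' @return a `connectome_cohort` list (subjects, matrices, truth if present).
#' @export
read_cohort <- function(dir) {
  subjects <- read_subjects(file.path(dir, "subjects.tsv"))
  man <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  matrices <- list()
  for (i in seq_len(nrow(man))) {
    id <- man$subject_id[i]
    matrices[[id]] <- list(
      functional = read_matrix(file.path(dir, man$functional[i]),
                               "functional", subject_id = id),
      structural = read_matrix(file.path(dir, man$structural[i]),
                               "structural", subject_id = id))
  }
  truth <- NULL
  tp <- file.path(dir, "ground_truth.json")
  if (file.exists(tp)) truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  structure(list(subjects = subjects, matrices = matrices, truth = truth),
            class = "connectome_cohort")
}

#' Write a metric or effect table as TSV with full numeric precision
#'
#' Numeric columns are written with 17 significant digits so a read/write
#' round trip is value-identical.
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_table <- function(df, path) {
  df <- as.data.frame(df)
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
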