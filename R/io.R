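#' Assemble and validate the three cohort tables
#'
#' Canonical in-memory container for one cohort: a patient x metabolite
#' concentration matrix (micromolar) with a parallel per-cell status matrix,
#' the metabolite -> family annotation, and the clinical table. Patients and
#' metabolites are canonicalized by sorting their ids, so downstream seeded
#' runs do not depend on file row order.
#'
#' @param concentrations Numeric matrix (patients x metabolites) with
#'   rownames = patient ids and colnames = metabolite names; cells that are
#'   below the limit of detection or missing are `NA`.
#' @param status Character matrix of the same shape with entries
#'   `"measured"`, `"below_LOD"` or `"missing"`.
#' @param annotations Named character vector mapping every metabolite name to
#'   one of [METABOLITE_FAMILIES].
#' @param clinical Data frame with one row per patient: `patient_id`,
#'   `admission_cause` (`"septic"`/`"cardiogenic"`), `apache2`, `sofa`,
#'   `n_organ_failures`, `icu_death`, `hospital_death` (logical), plus any
#'   additional covariate columns.
#'
#' @return An object of class `cohort_tables`.
#' @export
cohort_tables <- function(concentrations, status, annotations, clinical) {
  stopifnot(is.matrix(concentrations), is.matrix(status),
            all(dim(concentrations) == dim(status)),
            is.data.frame(clinical))
  pid_c <- rownames(concentrations)
  mets <- colnames(concentrations)
  if (is.null(pid_c) || is.null(mets)) {
    stop("concentrations must have patient ids as rownames and metabolite ",
         "names as colnames")
  }
  if (anyDuplicated(pid_c)) {
    stop("duplicated patient ids in concentrations: ",
         paste(unique(pid_c[duplicated(pid_c)]), collapse = ", "))
  }
  if (anyDuplicated(clinical$patient_id)) {
    stop("duplicated patient ids in clinical table: ",
         paste(unique(clinical$patient_id[duplicated(clinical$patient_id)]),
               collapse = ", "))
  }
  only_conc <- setdiff(pid_c, clinical$patient_id)
  only_clin <- setdiff(clinical$patient_id, pid_c)
  if (length(only_conc) || length(only_clin)) {
    stop("patient ids do not match between concentrations and clinical ",
         "tables; only in concentrations: [",
         paste(only_conc, collapse = ", "), "]; only in clinical: [",
         paste(only_clin, collapse = ", "), "]")
  }
  unann <- setdiff(mets, names(annotations))
  if (length(unann)) {
    stop("metabolites without family annotation: ",
         paste(unann, collapse = ", "))
  }
  annotations <- annotations[mets]
  bad_fam <- setdiff(unique(annotations), METABOLITE_FAMILIES)
  if (length(bad_fam)) {
    stop("unknown metabolite families: ", paste(bad_fam, collapse = ", "),
         "; allowed families are: ",
         paste(METABOLITE_FAMILIES, collapse = ", "))
  }
  bad_status <- setdiff(unique(as.vector(status)),
                        c("measured", "below_LOD", "missing"))
  if (length(bad_status)) {
    stop("invalid status values: ", paste(bad_status, collapse = ", "))
  }
  meas <- status == "measured"
  if (any(is.na(concentrations[meas]))) {
    stop("cells with status 'measured' must have a concentration value")
  }
  if (any(concentrations[meas] < 0)) {
    stop("measured concentrations must be non-negative")
  }
  # canonical order: patients and metabolites sorted by id
  po <- order(pid_c)
  mo <- order(mets)
  concentrations <- concentrations[po, mo, drop = FALSE]
  status <- status[po, mo, drop = FALSE]
  annotations <- annotations[mo]
  clinical <- clinical[order(clinical$patient_id), , drop = FALSE]
  rownames(clinical) <- NULL
  structure(list(concentrations = concentrations, status = status,
                 annotations = annotations, clinical = clinical),
            class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat(sprintf("cohort_tables: %d patients x %d metabolites\n",
              nrow(x$concentrations), ncol(x$concentrations)))
  st <- table(factor(x$status, c("measured", "below_LOD", "missing")))
  cat(sprintf("  cells: %d measured, %d below LOD, %d missing\n",
              st[["measured"]], st[["below_LOD"]], st[["missing"]]))
  cat("  families: ",
      paste(names(table(x$annotations)), table(x$annotations),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of patients in a cohort
#' @param tables A `cohort_tables` object.
#' @return Integer patient count.
#' @export
n_patients <- function(tables) nrow(tables$concentrations)

#' Read a cohort from delimited files
#'
#' Reads the concentration, annotation and clinical tables and validates
#' them into a [cohort_tables()] object. The concentration file is wide
#' (first column `patient_id`, one column per metabolite); cells equal to a
#' below-LOD sentinel get status `below_LOD`, empty cells or `NA` get status
#' `missing`. Field separator is inferred from the file extension (`.tsv` ->
#' tab, otherwise comma).
#'
#' @param conc_path Path to the wide concentration table.
#' @param annot_path Path to the two-column (`metabolite`, `family`)
#'   annotation table.
#' @param clinical_path Path to the clinical table (first column
#'   `patient_id`).
#' @param lod_sentinels Character values interpreted as below-LOD; kit export
#'   dialects differ, so this is configurable.
#' @return A `cohort_tables` object.
#' @export
read_cohort <- function(conc_path, annot_path, clinical_path,
                        lod_sentinels = c("<LOD", "< LOD", "<lod")) {
  conc_raw <- read_table_auto(conc_path, colClasses = "character")
  annot_raw <- read_table_auto(annot_path, colClasses = "character")
  clin <- read_table_auto(clinical_path)
  if (names(conc_raw)[1] != "patient_id" || names(clin)[1] != "patient_id") {
    stop("first column of the concentration and clinical tables must be ",
         "'patient_id'")
  }
  if (!all(c("metabolite", "family") %in% names(annot_raw))) {
    stop("annotation table needs columns 'metabolite' and 'family'")
  }
  pid <- as.character(conc_raw$patient_id)
  cells <- as.matrix(conc_raw[, -1, drop = FALSE])
  cells <- trimws(cells)
  dimnames(cells) <- list(pid, colnames(conc_raw)[-1])
  status <- matrix("measured", nrow(cells), ncol(cells),
                   dimnames = dimnames(cells))
  status[cells %in% lod_sentinels] <- "below_LOD"
  status[is.na(cells) | cells == "" | cells == "NA"] <- "missing"
  conc <- suppressWarnings(
    matrix(as.numeric(cells), nrow(cells), ncol(cells),
           dimnames = list(pid, colnames(cells)))
  )
  unparsed <- status == "measured" & is.na(conc)
  if (any(unparsed)) {
    bad <- which(unparsed, arr.ind = TRUE)[1, ]
    stop("non-numeric concentration value '",
         cells[bad[1], bad[2]], "' for patient ", pid[bad[1]],
         ", metabolite ", colnames(cells)[bad[2]],
         " (not a recognised below-LOD sentinel)")
  }
  conc[status != "measured"] <- NA_real_
  ann <- stats::setNames(annot_raw$family, annot_raw$metabolite)
  for (col in c("icu_death", "hospital_death")) {
    if (col %in% names(clin)) clin[[col]] <- as_logical_strict(clin[[col]], col)
  }
  clin$patient_id <- as.character(clin$patient_id)
  cohort_tables(conc, status, ann, clin)
}

as_logical_strict <- function(x, what) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "true", "1", 1)] <- TRUE
  out[x %in% c("FALSE", "false", "0", 0)] <- FALSE
  if (any(is.na(out) & !is.na(x))) {
    stop("column '", what, "' must be logical (TRUE/FALSE or 0/1)")
  }
  out
}

read_table_auto <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA", ...)
}

#' Write a cohort to delimited files
#'
#' Inverse of [read_cohort()]: writes `concentrations.csv` (below-LOD cells
#' as `<LOD`, missing cells empty), `annotations.csv` and `clinical.csv`
#' into `dir`, plus `true_labels.tsv` when the cohort carries planted
#' phenotype labels (see [simulate_cohort()]).
#'
#' @param cohort A `cohort_tables` object, or a `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  labels <- NULL
  if (inherits(cohort, "synthetic_cohort")) {
    labels <- cohort$true_labels
    cohort <- cohort$tables
  }
  stopifnot(inherits(cohort, "cohort_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- matrix(format_number(cohort$concentrations),
                  nrow(cohort$concentrations),
                  dimnames = dimnames(cohort$concentrations))
  cells[cohort$status == "below_LOD"] <- "<LOD"
  cells[cohort$status == "missing"] <- ""
  conc_df <- data.frame(patient_id = rownames(cells), cells,
                        check.names = FALSE)
  paths <- c(conc = file.path(dir, "concentrations.csv"),
             annot = file.path(dir, "annotations.csv"),
             clinical = file.path(dir, "clinical.csv"))
  utils::write.csv(conc_df, paths["conc"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(metabolite = names(cohort$annotations),
                              family = unname(cohort$annotations)),
                   paths["annot"], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$clinical, paths["clinical"], row.names = FALSE,
                   quote = FALSE)
  if (!is.null(labels)) {
    paths <- c(paths, labels = file.path(dir, "true_labels.tsv"))
    utils::write.table(
      data.frame(patient_id = names(labels), true_label = unname(labels)),
      paths["labels"], row.names = FALSE, sep = "\t", quote = FALSE)
  }
  invisible(paths)
}

format_number <- function(x) {
  out <- vapply(as.vector(x), function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE)
  }, character(1))
  out
}

#' Write a stage report to JSON
#'
#' Serializes any pipeline report (QC result, stability report, outcome
#' model report, ...) to JSON with full numeric precision, so a read-back
#' reproduces every numeric field exactly for integers and to full double
#' precision for floats.
#'
#' @param report A list-like stage report.
#' @param out_path Output file path.
#' @return Invisibly, `out_path`.
#' @seealso [read_report()]
#' @export
write_report <- function(report, out_path) {
  payload <- strip_unserializable(report)
  jsonlite::write_json(payload, out_path, auto_unbox = TRUE,
                       digits = I(17),
                       na = "null", null = "null", force = TRUE,
                       dataframe = "columns")
  invisible(out_path)
}

# drop closures / model objects that have no faithful JSON form
strip_unserializable <- function(x) {
  if (is.function(x) || inherits(x, "glm")) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_unserializable)
    x[!vapply(x, is.null, logical(1))]
  } else x
}

#' Read a report written by [write_report()]
#'
#' @param path JSON file path.
#' @return A list mirroring the written report.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
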