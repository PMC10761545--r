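#' Read a protein-level MS1 intensity table
#'
#' Reads a delimited-text export of protein-level MS1 peak areas (one row per
#' protein accession, one column per LC-MS run), as produced by search engines
#' such as PEAKS or MaxQuant, and validates it into the package's tidy
#' intensity-table form: a tibble whose first column is `accession` and whose
#' remaining columns are numeric per-run peak areas. A missing cell means the
#' protein was not identified/quantified in that run; it is stored as `NA` and
#' is distinct from a true zero.
#'
#' @param path Path to a TSV or CSV file.
#' @param accession_column Name of the column holding protein accessions.
#' @param run_columns Character vector of run-intensity column names. Default
#'   `NULL` takes every column other than `accession_column`.
#' @param missing_token Strings to interpret as a missing cell (besides an
#'   empty field).
#' @param delimiter Field delimiter; `NULL` (default) auto-detects tab vs
#'   comma from the first line.
#' @return A tibble with columns `accession` (character, unique) and one
#'   non-negative numeric column per run.
#' @seealso [write_intensity_table()], [assign_groups()]
#' @export
read_intensity_table <- function(path,
                                 accession_column = "accession",
                                 run_columns = NULL,
                                 missing_token = c("", "NA"),
                                 delimiter = NULL) {
  if (!file.exists(path)) {
    abort(paste0("intensity table file not found: ", path), class = "hcp_format_error")
  }
  delimiter <- delimiter %||% detect_delimiter(path)
  tbl <- readr::read_delim(path,
    delim = delimiter, na = missing_token,
    show_col_types = FALSE, progress = FALSE, trim_ws = TRUE
  )
  if (!accession_column %in% names(tbl)) {
    abort(paste0("column '", accession_column, "' not found in ", path),
      class = "hcp_format_error"
    )
  }
  run_columns <- run_columns %||% setdiff(names(tbl), accession_column)
  missing_runs <- setdiff(run_columns, names(tbl))
  if (length(missing_runs) > 0) {
    abort(paste0("run column(s) not found: ", paste(missing_runs, collapse = ", ")),
      class = "hcp_format_error"
    )
  }
  out <- tbl |>
    dplyr::select(accession = dplyr::all_of(accession_column), dplyr::all_of(run_columns)) |>
    dplyr::mutate(
      accession = as.character(.data$accession),
      dplyr::across(dplyr::all_of(run_columns), as.numeric)
    )
  validate_intensity_table(out)
}

#' Write an intensity table to delimited text
#'
#' Inverse of [read_intensity_table()]: cell values and the missingness
#' pattern round-trip exactly.
#'
#' @param table An intensity-table tibble.
#' @param path Output file path.
#' @param delimiter Field delimiter (default tab).
#' @param missing_token String written for missing cells.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(table, path, delimiter = "\t", missing_token = "") {
  table <- validate_intensity_table(table)
  readr::write_delim(table, path, delim = delimiter, na = missing_token, progress = FALSE)
  invisible(path)
}

#' Validate an intensity table
#'
#' Checks the invariants of the intensity-table form: an `accession` column of
#' unique identifiers, at least one run column, and all present intensities
#' non-negative.
#'
#' @param table A data frame to validate.
#' @return The table as a tibble, invisibly usable downstream.
#' @export
validate_intensity_table <- function(table) {
  table <- tibble::as_tibble(table)
  if (!"accession" %in% names(table)) {
    abort("intensity table must have an 'accession' column", class = "hcp_validation_error")
  }
  runs <- intensity_runs(table)
  if (length(runs) == 0 || nrow(table) == 0) {
    abort("intensity table needs at least one run and one accession",
      class = "hcp_validation_error"
    )
  }
  dup <- table$accession[duplicated(table$accession)]
  if (length(dup) > 0) {
    abort(paste0("duplicate accession(s): ", paste(unique(dup), collapse = ", ")),
      class = "hcp_validation_error"
    )
  }
  vals <- unlist(table[runs], use.names = FALSE)
  if (any(vals < 0, na.rm = TRUE)) {
    abort("negative intensity encountered", class = "hcp_validation_error")
  }
  table
}

#' Run identifiers of an intensity table
#'
#' @param table An intensity-table tibble.
#' @return Character vector of run column names (all columns but `accession`).
#' @export
intensity_runs <- function(table) {
  setdiff(names(table), "accession")
}

# tab unless the header has more commas than tabs
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_com > n_tab) "," else "\t"
}

#' Normalize protein accessions
#'
#' Strips database prefixes and description text from FASTA-style headers so
#' that identifiers from different sources match: `"sp|P69905|HBA_HUMAN"` and
#' `"P69905 Hemoglobin subunit alpha"` both become `"P69905"`.
#'
#' @param x Character vector of raw accessions or FASTA header lines.
#' @return Character vector of bare accessions.
#' @export
normalize_accessions <- function(x) {
  x <- sub("\\s.*$", "", trimws(x))
  parts <- strsplit(x, "|", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) >= 2 && p[[1]] %in% c("sp", "tr", "gi", "ref")) p[[2]] else p[[1]]
  }, character(1))
}

#' Read accessions from a FASTA file or plain list
#'
#' Accepts either a standard FASTA file (sequences are ignored; only header
#' accessions are used) or a plain text file with one accession per line.
#'
#' @param path File path.
#' @return Character vector of normalized accessions.
#' @export
read_accessions <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("accession file not found: ", path), class = "hcp_format_error")
  }
  first <- readLines(path, n = 1L)
  if (startsWith(trimws(first), ">")) {
    idx <- Biostrings::fasta.index(path)
    normalize_accessions(idx$desc)
  } else {
    lines <- trimws(readLines(path))
    normalize_accessions(lines[nzchar(lines)])
  }
}

#' Assign table accessions to target and host groups
#'
#' Partitions every accession of an intensity table into `"target"` (the
#' purified recombinant protein's chains), `"host"` (the host-cell or
#' calibrant proteome) or `"unassigned"`. Accessions are normalized with
#' [normalize_accessions()] on both sides before matching, so FASTA-style
#' headers and bare UniProt identifiers interoperate.
#'
#' @param table An intensity-table tibble.
#' @param target_ids Character vector of accessions, or the path of a FASTA /
#'   one-per-line text file.
#' @param host_ids Same, for the host/calibrant group.
#' @return A tibble with columns `accession` and `group`, one row per table
#'   accession, carrying a `counts` attribute (named integer vector).
#' @export
assign_groups <- function(table, target_ids, host_ids) {
  table <- validate_intensity_table(table)
  target_ids <- resolve_accession_input(target_ids)
  host_ids <- resolve_accession_input(host_ids)
  both <- intersect(target_ids, host_ids)
  if (length(both) > 0) {
    abort(paste0(
      "accession(s) in both target and host sets: ",
      paste(both, collapse = ", ")
    ), class = "hcp_conflict_error")
  }
  acc_norm <- normalize_accessions(table$accession)
  group <- dplyr::case_when(
    acc_norm %in% target_ids ~ "target",
    acc_norm %in% host_ids ~ "host",
    TRUE ~ "unassigned"
  )
  if (!any(group == "target")) {
    abort("no target accession present in the table; intensity ratio undefined",
      class = "hcp_validation_error"
    )
  }
  out <- tibble::tibble(accession = table$accession, group = group)
  counts <- c(
    target = sum(group == "target"),
    host = sum(group == "host"),
    unassigned = sum(group == "unassigned")
  )
  attr(out, "counts") <- counts
  out
}

resolve_accession_input <- function(x) {
  if (length(x) == 1 && is.character(x) && file.exists(x)) {
    read_accessions(x)
  } else {
    normalize_accessions(as.character(x))
  }
}

#' Known mass fraction of one calibrator level
#'
#' Computes the gravimetric design value of a spiked calibrator: the mass of
#' calibrant proteome per mass of target protein, from the weighed stock
#' aliquots and the stock mass fractions assigned by amino acid analysis.
#'
#' @param m_calibrant_stock Mass of calibrant stock solution weighed in (g).
#' @param c_calibrant_stock Protein mass fraction of the calibrant stock (mg/g).
#' @param m_target_stock Mass of target stock solution weighed in (g).
#' @param c_target_stock Protein mass fraction of the target stock (mg/g).
#' @return Known mass fraction `w_known` in mg calibrant protein per g target
#'   protein. Vectorized over all arguments.
#' @export
compute_design_level <- function(m_calibrant_stock, c_calibrant_stock,
                                 m_target_stock, c_target_stock) {
  args <- list(m_calibrant_stock, c_calibrant_stock, m_target_stock, c_target_stock)
  if (any(vapply(args, function(a) any(!is.finite(a) | a <= 0), logical(1)))) {
    abort("all stock masses and mass fractions must be positive and finite",
      class = "hcp_domain_error"
    )
  }
  1000 * (m_calibrant_stock * c_calibrant_stock) / (m_target_stock * c_target_stock)
}

#' Construct a calibrator design
#'
#' A calibrator design records, for each spike level, the known mass fraction
#' of calibrant proteome relative to target (mg/g) and the LC-MS runs that
#' measured it, plus the expanded (95 %) relative uncertainty of the
#' calibrator stock value assignment.
#'
#' @param level_id Character or integer vector of level identifiers, one entry
#'   per run (replicate runs repeat the level id).
#' @param w_known Numeric vector of known mass fractions (mg/g), one per run;
#'   constant within a level.
#' @param run_id Character vector of run labels matching intensity-table run
#'   columns.
#' @param U_cal_rel Expanded (95 %) relative uncertainty of the calibrant
#'   stock value assignment, in percent.
#' @param source_label Name of the calibrant proteome (e.g. `"E. coli"`).
#' @param mass_shares Optional named numeric vector of per-protein mass shares
#'   of the calibrant mix (names are accessions, values sum to 1). Required
#'   only by the protein-subsampling simulation's design rescaling.
#' @return A tibble of class `hcp_design` with columns `level_id`, `w_known`,
#'   `run_id` and attributes `U_cal_rel`, `source_label`, `mass_shares`.
#' @export
calibrator_design <- function(level_id, w_known, run_id, U_cal_rel,
                              source_label = "calibrant", mass_shares = NULL) {
  if (any(!is.finite(w_known) | w_known <= 0)) {
    abort("w_known must be positive", class = "hcp_validation_error")
  }
  if (!is.finite(U_cal_rel) || U_cal_rel < 0) {
    abort("U_cal_rel must be >= 0", class = "hcp_validation_error")
  }
  out <- tibble::tibble(
    level_id = as.character(level_id),
    w_known = as.numeric(w_known),
    run_id = as.character(run_id)
  )
  per_level <- out |>
    dplyr::distinct(.data$level_id, .data$w_known) |>
    dplyr::arrange(match(.data$level_id, unique(out$level_id)))
  if (anyDuplicated(per_level$level_id)) {
    abort("w_known must be constant within a level", class = "hcp_validation_error")
  }
  if (is.unsorted(per_level$w_known, strictly = TRUE)) {
    abort("w_known must be strictly increasing across levels",
      class = "hcp_validation_error"
    )
  }
  if (anyDuplicated(out$run_id)) {
    abort("run_id must be unique across the design", class = "hcp_validation_error")
  }
  if (!is.null(mass_shares)) {
    stopifnot(is.numeric(mass_shares), !is.null(names(mass_shares)))
    mass_shares <- mass_shares / sum(mass_shares)
  }
  attr(out, "U_cal_rel") <- U_cal_rel
  attr(out, "source_label") <- source_label
  attr(out, "mass_shares") <- mass_shares
  class(out) <- c("hcp_design", class(out))
  out
}

#' Read a calibrator design from a YAML file
#'
#' The file has global keys `source_label` and `U_cal_rel` (percent), an
#' optional `mass_shares` mapping (accession to mass share), and a `levels`
#' list whose entries give `level_id`, `w_known` (mg/g) and `run_ids`.
#'
#' @param path Path to a YAML design file.
#' @return An `hcp_design` tibble; see [calibrator_design()].
#' @export
read_calibrator_design <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("design file not found: ", path), class = "hcp_format_error")
  }
  y <- yaml::read_yaml(path)
  for (key in c("levels", "U_cal_rel")) {
    if (is.null(y[[key]])) {
      abort(paste0("design file missing '", key, "'"), class = "hcp_format_error")
    }
  }
  rows <- purrr::map_dfr(y$levels, function(lv) {
    tibble::tibble(
      level_id = as.character(lv$level_id),
      w_known = as.numeric(lv$w_known),
      run_id = as.character(unlist(lv$run_ids))
    )
  })
  shares <- if (!is.null(y$mass_shares)) unlist(y$mass_shares) else NULL
  calibrator_design(rows$level_id, rows$w_known, rows$run_id,
    U_cal_rel = as.numeric(y$U_cal_rel),
    source_label = y$source_label %||% "calibrant",
    mass_shares = shares
  )
}

#' Write a calibrator design to a YAML file
#'
#' @param design An `hcp_design` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibrator_design <- function(design, path) {
  levels <- design |>
    dplyr::group_by(.data$level_id, .data$w_known) |>
    dplyr::summarise(run_ids = list(.data$run_id), .groups = "drop") |>
    dplyr::arrange(.data$w_known)
  y <- list(
    source_label = attr(design, "source_label"),
    U_cal_rel = attr(design, "U_cal_rel"),
    levels = purrr::pmap(levels, function(level_id, w_known, run_ids) {
      list(level_id = level_id, w_known = w_known, run_ids = as.list(run_ids))
    })
  )
  shares <- attr(design, "mass_shares")
  if (!is.null(shares)) y$mass_shares <- as.list(shares)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
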