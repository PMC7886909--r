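#' Read a repertoire from tab-separated rearrangement tables
#'
#' Accepts both AIRR Community headers (`junction`, `junction_aa`,
#' `duplicate_count`, `productive`) and immunoSEQ-export-style headers
#' (`nucleotide`, `aminoAcid`, `count (templates/reads)` or `templates`,
#' `sequenceStatus` where `"In"` means productive). Other layouts are handled
#' through an explicit `mapping`.
#'
#' @param path Path to a TSV file, one row per unique rearrangement.
#' @param format `"auto"` (header sniffing), `"airr"`, `"immunoseq"`, or
#'   `"custom"` (requires `mapping`).
#' @param mapping Named character vector mapping canonical names
#'   (`cdr3_nt`, `cdr3_aa`, `count`, `productive`) to file column names.
#' @return A repertoire tibble (see [as_repertoire()]).
#' @export
read_repertoire <- function(path, format = c("auto", "airr", "immunoseq", "custom"),
                            mapping = NULL) {
  format <- match.arg(format)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cols <- names(raw)
  if (format == "auto") {
    format <- if (all(c("junction", "duplicate_count") %in% cols)) {
      "airr"
    } else if ("nucleotide" %in% cols) {
      "immunoseq"
    } else if (!is.null(mapping)) {
      "custom"
    } else {
      abort(paste0("cannot recognise repertoire columns in ", path,
                   "; supply an explicit `mapping`"),
            class = "tilmonitor_bad_format")
    }
  }
  map <- switch(format,
    airr = c(cdr3_nt = "junction", cdr3_aa = "junction_aa",
             count = "duplicate_count", productive = "productive"),
    immunoseq = c(cdr3_nt = "nucleotide", cdr3_aa = "aminoAcid",
                  count = if ("count (templates/reads)" %in% cols)
                    "count (templates/reads)" else "templates",
                  productive = "sequenceStatus"),
    custom = {
      if (is.null(mapping)) abort("format = 'custom' requires `mapping`",
                                  class = "tilmonitor_bad_format")
      mapping
    }
  )
  missing <- setdiff(unname(map[c("cdr3_nt", "count")]), cols)
  if (length(missing) > 0) {
    abort(paste0("missing repertoire columns in ", path, ": ",
                 paste(missing, collapse = ", ")),
          class = "tilmonitor_bad_format")
  }
  out <- tibble::tibble(
    cdr3_nt = as.character(raw[[map[["cdr3_nt"]]]]),
    count = as.numeric(raw[[map[["count"]]]])
  )
  out$cdr3_aa <- if (!is.na(map["cdr3_aa"]) && map[["cdr3_aa"]] %in% cols) {
    as.character(raw[[map[["cdr3_aa"]]]])
  } else NA_character_
  out$productive <- if (!is.na(map["productive"]) && map[["productive"]] %in% cols) {
    parse_productive(raw[[map[["productive"]]]])
  } else TRUE
  as_repertoire(out)
}

parse_productive <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  x %in% c("t", "true", "in", "productive", "1", "yes")
}

#' Write a repertoire as an AIRR-style TSV
#'
#' Emits columns `junction`, `junction_aa`, `duplicate_count`, `productive`
#' ("T"/"F"), one row per unique rearrangement, sorted by count descending
#' then junction (deterministic output for a given repertoire).
#'
#' @param rep A repertoire tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  rep <- as_repertoire(rep)
  out <- rep |>
    dplyr::arrange(dplyr::desc(count), cdr3_nt) |>
    dplyr::transmute(
      junction = cdr3_nt,
      junction_aa = cdr3_aa,
      duplicate_count = count,
      productive = ifelse(productive, "T", "F")
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read every repertoire TSV in a directory
#'
#' File names (without extension) become the element names, e.g. the
#' compartment/subset labels written by [write_cohort_fixtures()].
#'
#' @param dir Directory containing `.tsv` repertoire files.
#' @inheritParams read_repertoire
#' @return A named list of repertoire tibbles.
#' @export
read_repertoire_dir <- function(dir, format = "auto", mapping = NULL) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) {
    abort(paste0("no .tsv repertoire files found in ", dir),
          class = "tilmonitor_bad_format")
  }
  reps <- lapply(files, read_repertoire, format = format, mapping = mapping)
  names(reps) <- sub("\\.tsv$", "", basename(files))
  reps
}
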