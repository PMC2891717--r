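delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

check_count_col <- function(df, col, path) {
  x <- df[[col]]
  bad <- which(!is.finite(x) | x < 0 | x != round(x))
  if (length(bad))
    stop("in ", path, ": column '", col, "' must hold non-negative ",
         "integers; offending data row(s): ", paste(bad, collapse = ", "))
}

#' Read a dose-mortality bioassay table from CSV/TSV
#'
#' Expects a header with columns `dose_ug`, `n_exposed`, `n_dead`, and
#' optionally `label` and `sex`. Malformed rows are reported with their
#' row numbers.
#'
#' @param path path to a delimited text file (`.csv` or `.tsv`).
#' @return A [bioassay_table()] if the file holds a single label/sex
#'   combination, otherwise a named list of `bioassay_table`s split by
#'   `label` x `sex`.
#' @export
read_bioassay <- function(path) {
  df <- read.csv(path, sep = delim_for(path), stringsAsFactors = FALSE)
  need <- c("dose_ug", "n_exposed", "n_dead")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("in ", path, ": missing required column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(df$dose_ug) | df$dose_ug < 0))
    stop("in ", path, ": 'dose_ug' must be non-negative; offending row(s): ",
         paste(which(!is.finite(df$dose_ug) | df$dose_ug < 0),
               collapse = ", "))
  check_count_col(df, "n_exposed", path)
  check_count_col(df, "n_dead", path)
  bad <- which(df$n_dead > df$n_exposed)
  if (length(bad))
    stop("in ", path, ": n_dead exceeds n_exposed in row(s): ",
         paste(bad, collapse = ", "))
  key <- paste(df$label %||% "", df$sex %||% "", sep = "|")
  if (length(unique(key)) == 1) {
    lab <- trimws(gsub("\\|", " ", key[1]))
    return(bioassay_table(df$dose_ug, df$n_exposed, df$n_dead, label = lab))
  }
  lapply(split(df, key), function(d)
    bioassay_table(d$dose_ug, d$n_exposed, d$n_dead,
                   label = trimws(gsub("\\|", " ", d$label[1] %||% ""))))
}

#' Write a bioassay table to CSV
#'
#' @param table a [bioassay_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bioassay <- function(table, path) {
  stopifnot(inherits(table, "bioassay_table"))
  df <- data.frame(label = attr(table, "label") %||% "",
                   dose_ug = table$dose, n_exposed = table$n_exposed,
                   n_dead = table$n_dead)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tail-genotyping experiment from CSV (+ optional JSON sidecar)
#'
#' The CSV must have a header `cohort,c0,c1,c2` and rows with cohort
#' `alive` (all survivors genotyped) and `dead_sampled` (the genotyped
#' dead subsample). Experiment metadata -- `n_exposed` (required) and
#' `dose_label` -- may be given as arguments or in a JSON sidecar file
#' with the same basename and extension `.json`.
#'
#' @param path path to the CSV/TSV file.
#' @param n_exposed total exposed; overrides the sidecar.
#' @param dose_label dose description; overrides the sidecar.
#' @return A [tail_experiment()]. The sidecar's other fields (e.g. a
#'   surveyed `allele_frequency`) are attached as attribute `"meta"`.
#' @examples
#' fx <- system.file("extdata", "cyp6g1_ddt_tail.csv", package = "tailassoc")
#' read_tail_experiment(fx)
#' @export
read_tail_experiment <- function(path, n_exposed = NULL, dose_label = NULL) {
  df <- read.csv(path, sep = delim_for(path), stringsAsFactors = FALSE)
  need <- c("cohort", "c0", "c1", "c2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("in ", path, ": missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("c0", "c1", "c2")) check_count_col(df, col, path)
  meta <- list()
  sidecar <- sub("\\.[^.]+$", ".json", path)
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_exposed <- n_exposed %||% meta$n_exposed
  if (is.null(n_exposed))
    stop("n_exposed not supplied and no JSON sidecar found at ", sidecar)
  dose_label <- dose_label %||% meta$dose_label %||% ""
  row_of <- function(which) {
    i <- match(which, df$cohort)
    if (is.na(i)) stop("in ", path, ": no row with cohort '", which, "'")
    genotype_counts(df$c0[i], df$c1[i], df$c2[i])
  }
  out <- tail_experiment(row_of("alive"), row_of("dead_sampled"),
                         n_exposed = n_exposed, dose_label = dose_label)
  attr(out, "meta") <- meta
  out
}

#' Write a tail experiment to CSV plus JSON sidecar
#'
#' @param experiment a [tail_experiment()].
#' @param path output CSV path; the sidecar is written alongside with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_tail_experiment <- function(experiment, path) {
  stopifnot(inherits(experiment, "tail_experiment"))
  df <- data.frame(cohort = c("alive", "dead_sampled"),
                   rbind(as.integer(experiment$alive),
                         as.integer(experiment$dead_sampled)))
  names(df) <- c("cohort", "c0", "c1", "c2")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_exposed = experiment$n_exposed,
                            dose_label = experiment$dose_label),
                       sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Path to the packaged field-experiment fixture
#'
#' The packaged dataset holds the genotype counts of the high-dose arm of
#' a published DDT-resistance field experiment in *Drosophila
#' melanogaster*: 2500 flies exposed at 120 micrograms DDT per vial (a
#' nominal-LC95 dose), all 124 survivors genotyped at the Cyp6g1 resistance
#' locus, and 133 of the 2376 dead genotyped, with a focal (resistant)
#' allele frequency of 0.28 in the source population.
#'
#' @return Path to the packaged CSV (its JSON sidecar sits alongside).
#' @examples
#' read_tail_experiment(tailassoc_example())
#' @export
tailassoc_example <- function() {
  system.file("extdata", "cyp6g1_ddt_tail.csv", package = "tailassoc",
              mustWork = TRUE)
}
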