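#' Construct a colony-count table
#'
#' The package's interchange format for colony-size data: one row per
#' (dose, size) with an optional raw count, a frequency in percent of all
#' colonies, and a provenance tag. In tables produced by the synthetic
#' generator, sizes of 50 or more are pooled into the `n = 50` row (the
#' clonogenic class).
#'
#' @param dose Character dose labels (opaque; "0", "2", "8", ...).
#' @param n Integer colony sizes >= 1, unique within dose.
#' @param count Optional integer counts (>= 0, NA allowed for
#'   frequency-only rows).
#' @param frequency Optional frequencies in percent.
#' @param provenance One of `"observed"`, `"estimated"`, `"simulated"` per
#'   row.
#' @return A data frame of class `colony_table` with columns `dose`, `n`,
#'   `count`, `frequency`, `provenance`.
#' @export
colony_table <- function(dose, n, count = NA_integer_, frequency = NA_real_,
                         provenance = "observed") {
  if (length(n) == 0L) stop("empty table")
  d <- data.frame(dose = as.character(dose), n = as.integer(n),
                  count = as.integer(count), frequency = as.numeric(frequency),
                  provenance = as.character(provenance),
                  stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty table")
  if (any(d$n < 1L, na.rm = TRUE)) stop("colony sizes must be >= 1")
  if (anyDuplicated(d[c("dose", "n")])) stop("duplicate (dose, n) rows")
  if (any(!is.na(d$count) & d$count < 0L)) stop("negative counts")
  bad <- !d$provenance %in% c("observed", "estimated", "simulated")
  if (any(bad)) stop("provenance must be observed/estimated/simulated")
  if (all(is.na(d$count)) && all(is.na(d$frequency)))
    stop("table must contain counts or frequencies")
  class(d) <- c("colony_table", "data.frame")
  d
}

#' Read a colony-count table from delimited text
#'
#' Expects a header with columns `dose`, `n` and at least one of `count`
#' and `frequency` (percent); an optional `provenance` column defaults to
#' `"observed"`. The delimiter is auto-detected between comma and tab
#' unless given. Rows with a frequency but no count are legal
#' (frequency-only data, as in published figures). Malformed rows are
#' reported with their line numbers.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"comma"` or `"tab"`.
#' @return A `colony_table`.
#' @export
read_colony_table <- function(path, dialect = c("auto", "comma", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    header <- readLines(path, n = 1L)
    dialect <- if (grepl("\t", header)) "tab" else "comma"
  }
  sep <- if (dialect == "tab") "\t" else ","
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty table: ", path)
  need <- c("dose", "n")
  if (!all(need %in% names(d)))
    stop("missing required column(s): ", paste(setdiff(need, names(d)), collapse = ", "))
  if (!("count" %in% names(d)) && !("frequency" %in% names(d)))
    stop("table must contain a `count` or `frequency` column")
  if (is.null(d$count)) d$count <- NA_integer_
  if (is.null(d$frequency)) d$frequency <- NA_real_
  if (is.null(d$provenance)) d$provenance <- "observed"
  bad <- is.na(d$n) | d$n < 1 | (is.na(d$count) & is.na(d$frequency))
  if (any(bad))
    stop("malformed row(s) at line(s): ",
         paste(which(bad) + 1L, collapse = ", "))
  colony_table(d$dose, d$n, d$count, d$frequency, d$provenance)
}

#' Write a colony-count table as delimited text
#'
#' Round-trip stable with [read_colony_table()]: writing and re-reading
#' yields an identical canonical table.
#'
#' @param table A `colony_table`.
#' @param path Output path.
#' @param dialect `"comma"` (default) or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(table, path, dialect = c("comma", "tab")) {
  stopifnot(inherits(table, "colony_table"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tab") "\t" else ","
  write.table(as.data.frame(table), path, sep = sep, quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Generate a synthetic colony-count table from the branching model
#'
#' Fixture generator emulating the structure of scored colony-formation
#' data: colony sizes are drawn for `n_colonies` independently plated
#' cells, either as a multinomial sample over the analytic branching-model
#' size distribution (`mode = "analytic"`; sizes 1-49 from
#' [pmf_schedule()], all remaining mass — large abortive colonies and
#' indefinitely proliferating clones — pooled into the clonogenic
#' `n = 50` class) or by running the lattice simulator (`mode =
#' "lattice"`). Frequencies are percent of all plated colonies, so the
#' empirical frequencies converge to the generating pmf as `n_colonies`
#' grows.
#'
#' @param schedule A [p1_schedule].
#' @param n_colonies Number of plated cells (default 50000, an assay-scale
#'   batch).
#' @param seed Integer seed; draws are bit-reproducible.
#' @param mode `"analytic"` or `"lattice"`.
#' @param dose Dose label for the table (default `"synthetic"`).
#' @param config [lattice_config()] for `mode = "lattice"`.
#' @return A `colony_table` with provenance `"simulated"`.
#' @export
generate_synthetic_counts <- function(schedule, n_colonies = 50000L, seed = 1L,
                                      mode = c("analytic", "lattice"),
                                      dose = "synthetic",
                                      config = lattice_config()) {
  stopifnot(inherits(schedule, "p1_schedule"))
  mode <- match.arg(mode)
  if (n_colonies < 1L) stop("`n_colonies` must be >= 1")
  if (mode == "analytic") {
    set.seed(seed)
    pmf <- pmf_schedule(schedule, 49L)
    probs <- c(pmf, max(0, 1 - sum(pmf)))   # last class: >= 50 cells
    counts <- as.integer(rmultinom(1L, n_colonies, probs))
    sizes <- c(1:49, 50L)
  } else {
    res <- run_batch(schedule, config, n_inocula = n_colonies, n_sets = 1L,
                     seed = seed)
    fs <- pmin(res$final_sizes, 50L)        # pool the clonogenic class
    tab <- table(factor(fs, levels = 1:50))
    counts <- as.integer(tab)
    sizes <- 1:50
  }
  keep <- counts > 0L
  colony_table(dose = dose, n = sizes[keep], count = counts[keep],
               frequency = 100 * counts[keep] / n_colonies,
               provenance = "simulated")
}

#' Extract one dose from a colony table as a size distribution
#'
#' @param table A `colony_table`.
#' @param dose Dose label to extract.
#' @param sizes Sizes to keep (default `2:15`, the scored abortive range
#'   used for fitting; the pooled `n = 50` class is never a genuine size).
#' @param estimate_f1 Add the inferred 1-cell class via
#'   [add_estimated_f1()]?
#' @return A [colony_size_distribution()].
#' @export
table_to_distribution <- function(table, dose, sizes = 2:15,
                                  estimate_f1 = TRUE) {
  stopifnot(inherits(table, "colony_table"))
  rows <- table[table$dose == as.character(dose) & table$n %in% sizes, ]
  if (nrow(rows) == 0L) stop("no rows for dose ", dose)
  freq <- rows$frequency
  if (all(is.na(freq))) {
    tot <- sum(table$count[table$dose == as.character(dose)], na.rm = TRUE)
    freq <- 100 * rows$count / tot
  }
  d <- colony_size_distribution(dose, rows$n, freq)
  if (estimate_f1 && !(1L %in% d$n)) d <- add_estimated_f1(d) else d
}

#' Read a flat key-value lattice configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognized keys
#' are exactly the arguments of [lattice_config()].
#'
#' @param path File path.
#' @return A [lattice_config()].
#' @export
read_lattice_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  allowed <- names(formals(lattice_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "rcd_when_blocked") return(toupper(vals[i]) %in% c("TRUE", "1", "YES"))
    as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(lattice_config, args)
}
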