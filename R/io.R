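# Streaming interface and position files. The stream contract matches the
# original methyl_diff program: four whitespace-separated integers per line
# on stdin (non-converted and converted reads for sample 1, then sample 2),
# one probability P(p1 > p2) per line on stdout.

#' Parse one four-integer count line
#'
#' By default the first four whitespace-separated fields are read as
#' `nc1 c1 nc2 c2`; any further fields are ignored. `fields` remaps which
#' columns carry the counts, so count columns embedded in a wider table can
#' be fed through without reshaping.
#'
#' @param line Single character string.
#' @param line_number Optional line number used in error messages.
#' @param fields Length-4 integer vector: 1-based column indices of
#'   `nc1, c1, nc2, c2`.
#' @return Integer vector `c(nc1, c1, nc2, c2)`.
#' @examples
#' parse_count_line("3 1 1 3")
#' parse_count_line("chr1 500 3 1 1 3", fields = 3:6)
#' @export
parse_count_line <- function(line, line_number = NA, fields = 1:4) {
  if (length(fields) != 4 || any(fields < 1)) {
    stop("fields must be four 1-based column indices", call. = FALSE)
  }
  parts <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  where <- if (is.na(line_number)) "" else paste0(" at line ", line_number)
  if (length(parts) < max(fields)) {
    stop("expected at least ", max(fields), " fields", where, call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(parts[fields]))
  if (any(is.na(v)) || any(v != round(v)) || any(v < 0)) {
    stop("count fields must be non-negative integers", where,
         ": '", line, "'", call. = FALSE)
  }
  as.integer(v)
}

.format_prob <- function(x, digits) {
  trimws(formatC(x, digits = digits, format = "g"))
}

#' Stream differential-methylation probabilities line by line
#'
#' Reads count lines (four integers each; blank lines and `#` comments are
#' skipped) and writes one output line per input line with `P(p1 > p2)` at a
#' fixed number of significant digits, preserving input order. With
#' `columns = "all"` each line additionally carries the posterior means and
#' variances and the Fisher and Z p-values, tab-separated. Processing is
#' single pass and constant memory in the number of lines.
#'
#' @param input Connection or file path to read from (`"stdin"` works).
#' @param output Connection or file path to write to (default standard
#'   output).
#' @param digits Significant digits of the printed probability.
#' @param columns `"prob"` for the bare probability, `"all"` for
#'   `prob mean1 var1 mean2 var2 fisher_p z_p`.
#' @param on_error `"fail"` stops at the first malformed line; `"skip"`
#'   warns and drops it.
#' @param fields 1-based indices of the `nc1, c1, nc2, c2` columns (see
#'   [parse_count_line()]).
#' @param prior Beta prior pseudo-counts.
#' @return Invisibly, the number of lines emitted.
#' @examples
#' tmp <- tempfile()
#' writeLines(c("3 1 1 3", "0 0 0 0"), tmp)
#' stream_diff(tmp)
#' @export
stream_diff <- function(input, output = stdout(), digits = 6L,
                        columns = c("prob", "all"),
                        on_error = c("fail", "skip"), fields = 1:4,
                        prior = c(1, 1)) {
  columns <- match.arg(columns)
  on_error <- match.arg(on_error)
  if (is.character(input)) {
    con_in <- file(input, open = "r")
    on.exit(close(con_in), add = TRUE)
  } else {
    con_in <- input
  }
  if (is.character(output)) {
    con_out <- file(output, open = "w")
    on.exit(close(con_out), add = TRUE)
  } else {
    con_out <- output
  }

  emitted <- 0L
  line_no <- 0L
  repeat {
    lines <- readLines(con_in, n = 5000L)
    if (length(lines) == 0) break
    for (line in lines) {
      line_no <- line_no + 1L
      if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
      counts <- tryCatch(parse_count_line(line, line_no, fields = fields),
                         error = function(e) e)
      if (inherits(counts, "error")) {
        if (on_error == "fail") stop(conditionMessage(counts), call. = FALSE)
        warning(conditionMessage(counts), call. = FALSE)
        next
      }
      res <- diff_methylation(counts[1], counts[2], counts[3], counts[4],
                              prior = prior)
      out <- .format_prob(res$prob_greater, digits)
      if (columns == "all") {
        fp <- fisher_one_tailed(counts[1], counts[2], counts[3], counts[4])$p_value
        zp <- z_score_test(counts[1], counts[2], counts[3], counts[4],
                           prior = prior)
        out <- paste(out,
                     .format_prob(res$mean1, digits), .format_prob(res$var1, digits),
                     .format_prob(res$mean2, digits), .format_prob(res$var2, digits),
                     .format_prob(fp, digits), .format_prob(zp, digits),
                     sep = "\t")
      }
      writeLines(out, con_out)
      emitted <- emitted + 1L
    }
  }
  invisible(emitted)
}

#' Read a six-column position file
#'
#' Tab- or whitespace-separated columns `chrom pos nc1 c1 nc2 c2`; a header
#' row is auto-detected (non-integer second field) and skipped. Rows must
#' have exactly six fields; malformed rows raise an error naming the row.
#' Unsorted positions within a chromosome produce a warning, not an error.
#'
#' @param path File path.
#' @return Data frame with columns `chrom` (character), `pos`, `nc1`, `c1`,
#'   `nc2`, `c2` (integers).
#' @export
read_position_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      nc1 = integer(), c1 = integer(),
                      nc2 = integer(), c2 = integer()))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  first <- fields[[1]]
  has_header <- length(first) >= 2 &&
    is.na(suppressWarnings(as.integer(first[2])))
  row_offset <- 0L
  if (has_header) {
    fields <- fields[-1]
    row_offset <- 1L
  }
  n <- length(fields)
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      nc1 = integer(), c1 = integer(),
                      nc2 = integer(), c2 = integer()))
  }
  widths <- lengths(fields)
  if (any(widths != 6L)) {
    bad <- which(widths != 6L)[1]
    stop("row ", bad + row_offset, " has ", widths[bad],
         " fields; expected 6 (chrom pos nc1 c1 nc2 c2)", call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  num <- suppressWarnings(apply(mat[, 2:6, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 5)
  bad <- which(rowSums(is.na(num) | num != round(num) | num < 0) > 0)
  if (length(bad) > 0) {
    stop("row ", bad[1] + row_offset,
         " has non-integer or negative numeric fields", call. = FALSE)
  }
  if (any(num[, 1] < 1)) {
    stop("positions must be >= 1 (1-based coordinates)", call. = FALSE)
  }
  df <- data.frame(chrom = mat[, 1], pos = as.integer(num[, 1]),
                   nc1 = as.integer(num[, 2]), c1 = as.integer(num[, 3]),
                   nc2 = as.integer(num[, 4]), c2 = as.integer(num[, 5]))
  unsorted <- tapply(df$pos, df$chrom, is.unsorted, strictly = TRUE)
  if (any(unsorted)) {
    warning("positions are not strictly increasing within chromosome(s): ",
            paste(names(unsorted)[unsorted], collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a synthetic position file
#'
#' Generates a six-column position file whose counts follow the binomial
#' processes of `config`: flanking thirds of the positions are
#' negative-control sites (both samples at `p_null`) and the middle third is
#' a differentially methylated block (`p1_alt` vs `p2_alt`), so the file
#' exercises both the streaming interface and the track-smoothing layer.
#' Byte-identical output for a fixed configuration.
#'
#' @param config A [simulation_config()]; `n_sites` is ignored in favour of
#'   `n_positions`.
#' @param n_positions Number of data rows.
#' @param chrom Chromosome label.
#' @param spacing Fixed distance between consecutive positions, in bases.
#' @param path Output file path.
#' @return Invisibly, the written data frame.
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' generate_fixture(simulation_config(depth1 = 10, depth2 = 10, seed = 3),
#'                  n_positions = 30, path = tmp)
#' head(read_position_file(tmp))
#' @export
generate_fixture <- function(config, n_positions, chrom = "chrS",
                             spacing = 100L, path) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be created by simulation_config()", call. = FALSE)
  }
  if (n_positions < 1) stop("n_positions must be >= 1", call. = FALSE)
  n <- as.integer(n_positions)
  dmr_start <- floor(n / 3) + 1L
  dmr_end <- min(n, floor(2 * n / 3))
  is_dmr <- seq_len(n) >= dmr_start & seq_len(n) <= dmr_end
  null_sites <- simulate_site_pairs(config$p_null, config$p_null,
                                    config$depth1, config$depth2,
                                    n_sites = n, seed = config$seed)
  alt_sites <- simulate_site_pairs(config$p1_alt, config$p2_alt,
                                   config$depth1, config$depth2,
                                   n_sites = n, seed = config$seed + 1L)
  counts <- null_sites
  counts[is_dmr, ] <- alt_sites[is_dmr, ]
  df <- data.frame(chrom = chrom,
                   pos = seq_len(n) * as.integer(spacing),
                   counts)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("chrom\tpos\tnc1\tc1\tnc2\tc2",
               do.call(paste, c(df, sep = "\t"))), con)
  invisible(df)
}
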