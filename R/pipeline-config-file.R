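#' Read a pipeline configuration from a flat key-value file
#'
#' Parses a plain-text file of `block.parameter = value` lines (`#` starts
#' a comment) into a [pipeline_config()]. Keys prefixed `sim.` set
#' [sim_config()] fields; other prefixes address the stage parameter
#' blocks (`snp.`, `windows.`, `assign.`, `counts.`, `imprinting.`,
#' `accession.`, `bs.`, `dmr.`, `allele_dmr.`, `te.`, `cluster.`); the
#' bare keys `outdir` and `write_reads` are passed through.
#'
#' @param path configuration file.
#' @param seed optional seed overriding `sim.seed`.
#' @param outdir optional output directory overriding `outdir`.
#' @return a [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path, seed = NULL, outdir = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  parse_val <- function(v)
    utils::type.convert(v, as.is = TRUE, tryLogical = TRUE)
  sim_args <- list()
  blocks <- list()
  extra <- list()
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      extra[[parts[1]]] <- parse_val(vals[i])
    } else if (parts[1] == "sim") {
      sim_args[[parts[2]]] <- parse_val(vals[i])
    } else {
      blocks[[parts[1]]][[parts[2]]] <- parse_val(vals[i])
    }
  }
  if (!is.null(seed)) sim_args$seed <- as.integer(seed)
  args <- c(list(sim = do.call(sim_config, sim_args)), blocks)
  if (!is.null(outdir)) args$outdir <- outdir
  else if (!is.null(extra$outdir)) args$outdir <- extra$outdir
  if (!is.null(extra$write_reads)) args$write_reads <- extra$write_reads
  do.call(pipeline_config, args)
}
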