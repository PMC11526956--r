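#' Write a population snapshot as plain text
#'
#' One individual per line; one tab-separated field per protein (order
#' `R, A, I, U, D` for hosts, `P` for pathogens); within a field the three
#' domains as 0/1 character strings in the order `receiver|neutral|sender`,
#' separated by `|`. Site 1 is the leftmost character. The header line
#' records `L` and the protein labels.
#'
#' @param pop A `host_population` or `pathogen_population`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  L <- population_L(pop)
  proteins <- if (inherits(pop, "host_population")) host_proteins() else "P"
  header <- paste0("#L=", L, " proteins=", paste(proteins, collapse = ","))
  lines <- apply(pop, 1L, function(bits) {
    paste(vapply(seq_along(proteins), function(p) {
      base <- (p - 1L) * 3L * L
      paste(vapply(1:3, function(d) {
        paste(bits[base + (d - 1L) * L + seq_len(L)], collapse = "")
      }, character(1)), collapse = "|")
    }, character(1)), collapse = "\t")
  })
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a population snapshot written by [write_population()]
#'
#' @param path Snapshot file.
#' @return A `host_population` or `pathogen_population` matrix.
#' @export
read_population <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#L=")) {
    stop("not a population snapshot (missing header): ", path)
  }
  hdr <- regmatches(lines[1L],
                    regexec("^#L=([0-9]+) proteins=([A-Z,]+)$", lines[1L]))[[1]]
  if (length(hdr) != 3L) stop("malformed snapshot header: ", lines[1L])
  L <- as.integer(hdr[2L])
  proteins <- strsplit(hdr[3L], ",", fixed = TRUE)[[1]]
  body <- lines[-1L]
  m <- t(vapply(body, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(proteins)) stop("wrong field count in snapshot line")
    as.integer(strsplit(paste(gsub("|", "", fields, fixed = TRUE),
                              collapse = ""), "")[[1]])
  }, integer(length(proteins) * 3L * L), USE.NAMES = FALSE))
  cls <- if (identical(proteins, "P")) "pathogen_population" else "host_population"
  new_population(m, L, cls)
}

#' Write per-generation records as tab-separated text
#'
#' @param records A run's `records` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run metadata (configuration and seed) as JSON
#'
#' @param config An [evolution_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path) {
  obj <- list(
    n = config$n, generations = config$generations, theta = config$theta,
    alpha = config$alpha, beta = config$beta, MH = config$MH, MP = config$MP,
    L = config$L, sample_interval = config$sample_interval,
    saturation_threshold = config$saturation_threshold,
    mu_overrides = as.list(config$mu_overrides),
    seed = config$seed,
    dynamics = list(phi = as.list(config$dynamics$phi),
                    pi = config$dynamics$pi, P0 = config$dynamics$P0,
                    T = config$dynamics$T, dt = config$dynamics$dt,
                    force_inhibitory_IP = config$dynamics$force_inhibitory_IP),
    package_version = as.character(utils::packageVersion("nflevo"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
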