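# Flat key/value configuration with dotted nesting, diff-able run records.

#' Default run configuration
#'
#' The defaults encode the method's standard settings: 30-60\% training
#' mask ratio, 5 mm inference margin, 16 px attention patches, perceptual
#' weight 64, learning rate 0.001 halved every 5 epochs, and a
#' size-dependent batch (16 up to 256 px, 4 at 512 px).
#'
#' @param imageSize slice side in pixels, default 256
#' @return named list of configuration values
#' @export
defaultRunConfig <- function(imageSize = 256L) {
  list(seed = 1L, image_size = as.integer(imageSize),
       mask_ratio_lo = 0.30, mask_ratio_hi = 0.60, margin_mm = 5,
       patch_size = 16L, lambda_perc = 64, lr = 0.001, lr_halve_every = 5L,
       batch = defaultBatchSize(c(imageSize, imageSize)),
       use_cra = TRUE, use_flip = TRUE)
}

.parseConfigValue <- function(v) {
  v <- trimws(v)
  if (v %in% c("TRUE", "true", "yes")) return(TRUE)
  if (v %in% c("FALSE", "false", "no")) return(FALSE)
  if (grepl(",", v)) {
    parts <- strsplit(v, ",")[[1L]]
    nums <- suppressWarnings(as.numeric(parts))
    if (!any(is.na(nums))) return(nums)
    return(trimws(parts))
  }
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' Read a flat key/value configuration file
#'
#' One \code{key: value} pair per line; \code{#} starts a comment; dots in
#' keys express nesting but are kept flat. Values parse to logical,
#' numeric, numeric vectors (comma-separated) or strings.
#'
#' @param path configuration file
#' @return named list
#' @export
readConfigFile <- function(path) {
  if (!file.exists(path)) stop("readConfigFile: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl(":", lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1L]]
    out[[trimws(kv[1L])]] <- .parseConfigValue(kv[2L])
  }
  out
}

#' Merge configuration sources (later sources win)
#' @param ... named lists, in increasing priority (file < flags)
#' @return named list
#' @export
mergeConfig <- function(...) {
  out <- list()
  for (cfg in list(...)) if (length(cfg)) out <- modifyList(out, cfg)
  out
}

# Parse --key=value flags into a named list; bare --flag becomes TRUE.
.parseFlags <- function(argv) {
  out <- list()
  for (a in argv) {
    if (!startsWith(a, "--")) next
    body <- substring(a, 3L)
    if (grepl("=", body)) {
      kv <- regmatches(body, regexpr("=", body), invert = TRUE)[[1L]]
      out[[kv[1L]]] <- .parseConfigValue(kv[2L])
    } else out[[body]] <- TRUE
  }
  out
}
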