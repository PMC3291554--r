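#' @include simulate.R
NULL

#' Write a recording to a delimited text file
#'
#' Comma-separated, one row per sample, with commented header lines
#' (\code{# key=value}) carrying the sampling interval, channel map and
#' provenance metadata.  The round trip through
#' \code{\link{readRecording}} is lossless (numbers are printed with 17
#' significant digits).
#'
#' @param rec a \code{\link{Recording}}.
#' @param path output path.
#' @param includeHidden store the true hidden-state columns as well.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, includeHidden = TRUE) {
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(sprintf("# sample_interval=%s", num(rec@sampleInterval)),
           sprintf("# channel_map=%s", paste(rec@channelMap, collapse = ",")))
  for (key in names(rec@meta)) {
    v <- rec@meta[[key]]
    if (is.null(v) || !length(v)) next
    val <- if (key == "theta_true")
      paste(sprintf("%s:%s", names(v), vapply(v, num, "")), collapse = ";")
    else if (is.numeric(v)) num(v) else as.character(v)
    hdr <- c(hdr, sprintf("# %s=%s", key, val))
  }
  hid <- if (includeHidden && nrow(rec@hidden)) rec@hidden else NULL
  tab <- cbind(time_ms = sampleTimes(rec), rec@iInj, rec@y,
               if (!is.null(hid)) {
                 h <- hid; colnames(h) <- paste0("hidden_", colnames(hid)); h
               })
  body <- apply(tab, 1, function(r) paste(num(r), collapse = ","))
  writeLines(c(hdr, paste(colnames(tab), collapse = ","), body), path)
  invisible(path)
}

#' Read a recording written by \code{\link{writeRecording}}
#'
#' @param path input path.
#' @return a \code{\link{Recording}}.
#' @export
readRecording <- function(path) {
  lines <- readLines(path)
  isHdr <- grepl("^#", lines)
  nHdrTotal <- which(!isHdr)[1] - 1L
  if (is.na(nHdrTotal)) stop("parse error: no data found in ", path)
  meta <- list()
  for (i in seq_len(nHdrTotal)) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop(sprintf("parse error at line %d: expected '# key=value'", i))
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  if (is.null(meta$sample_interval))
    stop("parse error: missing 'sample_interval' header")
  header <- strsplit(lines[nHdrTotal + 1L], ",", fixed = TRUE)[[1]]
  body <- lines[-seq_len(nHdrTotal + 1L)]
  body <- body[nzchar(body)]
  cells <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(cells)
  if (any(nfield != length(header))) {
    bad <- which(nfield != length(header))[1]
    stop(sprintf("parse error at line %d: %d fields, expected %d",
                 nHdrTotal + 1L + bad, nfield[bad], length(header)))
  }
  tab <- matrix(as.numeric(unlist(cells)), nrow = length(cells),
                byrow = TRUE, dimnames = list(NULL, header))
  if (anyNA(tab)) {
    bad <- which(apply(tab, 1, anyNA))[1]
    stop(sprintf("parse error at line %d: non-numeric value",
                 nHdrTotal + 1L + bad))
  }
  iCols <- grep("^i_inj_", header)
  yCols <- grep("^v_obs_", header)
  hCols <- grep("^hidden_", header)
  chan <- as.integer(strsplit(meta$channel_map %||% "1", ",")[[1]])
  hid <- if (length(hCols)) {
    h <- tab[, hCols, drop = FALSE]
    colnames(h) <- sub("^hidden_", "", header[hCols])
    h
  } else matrix(numeric(), 0, 0)
  thetaTrue <- NULL
  if (!is.null(meta$theta_true)) {
    parts <- strsplit(strsplit(meta$theta_true, ";", fixed = TRUE)[[1]], ":",
                      fixed = TRUE)
    thetaTrue <- lapply(parts, function(p) as.numeric(p[2]))
    names(thetaTrue) <- vapply(parts, `[`, "", 1)
  }
  numOrNull <- function(x) if (is.null(x)) NULL else as.numeric(x)
  new("Recording", sampleInterval = as.numeric(meta$sample_interval),
      iInj = tab[, iCols, drop = FALSE], y = tab[, yCols, drop = FALSE],
      channelMap = chan, hidden = hid,
      meta = list(model = meta$model,
                  seed = numOrNull(meta$seed),
                  theta_true = thetaTrue,
                  sigma_sys = numOrNull(meta$sigma_sys),
                  sigma_obs = numOrNull(meta$sigma_obs),
                  delta = numOrNull(meta$delta),
                  k = numOrNull(meta$k)))
}
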