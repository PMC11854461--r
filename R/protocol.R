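#' Load the Simple Question Task protocol
#'
#' Reads the packaged 10-question protocol (question text, correct O/X key,
#' audio duration in milliseconds) and returns it as an
#' \linkS4class{SQTProtocol}. The response window is fixed at 10 s.
#'
#' @param path optional path to an alternative protocol TSV with columns
#'   \code{index}, \code{text}, \code{correct_key}, \code{listening_time_ms}.
#' @return an \linkS4class{SQTProtocol}.
#' @examples
#' p <- loadProtocol()
#' questionTable(p)$listening_time_ms
#' @export
loadProtocol <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sqt_protocol.tsv", package = "adspectrum",
                        mustWork = TRUE)
  }
  q <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, quote = ""),
    error = function(e) stop("protocol fixture unreadable: ", conditionMessage(e)))
  need <- c("index", "text", "correct_key", "listening_time_ms")
  if (!all(need %in% names(q)))
    stop("protocol fixture is corrupt: missing columns ",
         paste(setdiff(need, names(q)), collapse = ", "))
  q <- q[order(q$index), need]
  q$listening_time_ms <- as.numeric(q$listening_time_ms)
  if (any(is.na(q$listening_time_ms)))
    stop("protocol fixture is corrupt: non-numeric listening time")
  new("SQTProtocol", questions = q, responseWindowMs = 10000)
}

#' @describeIn loadProtocol the protocol's question table (data.frame).
#' @param protocol an \linkS4class{SQTProtocol}.
#' @export
questionTable <- function(protocol) {
  stopifnot(is(protocol, "SQTProtocol"))
  protocol@questions
}

#' @describeIn loadProtocol the protocol's response window in milliseconds.
#' @export
responseWindow <- function(protocol) {
  stopifnot(is(protocol, "SQTProtocol"))
  protocol@responseWindowMs
}
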