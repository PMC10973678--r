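#' Encode one measurement frame as the device's ASCII message
#'
#' The serial stream frame is the literal header `"\r\nmagnitudes:"`,
#' followed by each channel magnitude formatted as a fixed 4-decimal float
#' and a `","` separator, and terminated by `"\r\n"`. Decoding an encoded
#' frame reproduces the magnitudes to 4 decimal places.
#'
#' @param magnitudes Numeric vector of non-negative, finite channel
#'   magnitudes (volts).
#' @return A single character string.
#' @examples
#' encode_frame(1.1234)  # "\r\nmagnitudes:1.1234,\r\n"
#' @export
encode_frame <- function(magnitudes) {
  magnitudes <- as.numeric(magnitudes)
  if (any(!is.finite(magnitudes)) || any(magnitudes < 0))
    stop("frame magnitudes must be finite and non-negative", call. = FALSE)
  body <- if (length(magnitudes)) paste0(sprintf("%.4f", magnitudes), ",", collapse = "") else ""
  paste0("\r\nmagnitudes:", body, "\r\n")
}

#' Incremental decoder for the device's serial stream
#'
#' Creates a stateful decoder that can be fed arbitrary chunks of the
#' ASCII stream (e.g. as read from a serial capture); complete frames are
#' emitted as they are terminated, and a partial trailing frame is kept in
#' the internal buffer across calls. The parser is lenient: it accepts the
#' header with or without the leading CRLF, and both `","` and `", "`
#' separators with an optional trailing separator. A malformed numeric
#' token yields a per-frame error record rather than an abort.
#'
#' @return A list of functions: `feed(chunk)` returning the list of frames
#'   completed by that chunk, `pending()` returning the current unparsed
#'   buffer, and `reset()`.
#'
#' Each decoded frame is a list with `magnitudes` (numeric vector, `NA`
#' for unparseable tokens), `valid` (no malformed tokens), and `errors`
#' (character vector naming bad tokens and their positions).
#' @seealso [decode_stream()]
#' @export
frame_decoder <- function() {
  buffer <- ""
  parse_body <- function(body) {
    if (body == "") {
      return(list(magnitudes = numeric(0), valid = TRUE, errors = character(0)))
    }
    tokens <- strsplit(body, ",[ ]?")[[1]]
    vals <- suppressWarnings(as.numeric(tokens))
    bad <- which(is.na(vals) | tokens == "")
    list(magnitudes = vals, valid = length(bad) == 0,
         errors = if (length(bad)) sprintf("measurement %d: unparseable token '%s'",
                                           bad, tokens[bad]) else character(0))
  }
  feed <- function(chunk) {
    buffer <<- paste0(buffer, chunk)
    frames <- list()
    repeat {
      start <- regexpr("magnitudes:", buffer, fixed = TRUE)
      if (start < 0) break
      rest_at <- start + attr(start, "match.length")
      rest <- substr(buffer, rest_at, nchar(buffer))
      end <- regexpr("\r\n", rest, fixed = TRUE)
      if (end < 0) break                      # incomplete frame: wait for more
      body <- substr(rest, 1, end - 1)
      frames[[length(frames) + 1L]] <- parse_body(body)
      buffer <<- substr(rest, end + 2, nchar(rest))
    }
    frames
  }
  list(feed = feed,
       pending = function() buffer,
       reset = function() { buffer <<- ""; invisible(NULL) })
}

#' Decode a complete serial capture into frames
#'
#' @param text Character string (or vector, concatenated) holding the raw
#'   ASCII stream.
#' @param n_expected Optional expected measurement count per frame (e.g.
#'   [count_measurements()] of the active protocol); frames with a
#'   different count are flagged invalid with a count-mismatch error.
#' @return List of frames (see [frame_decoder()] for the frame structure).
#' @examples
#' f <- decode_stream(encode_frame(c(1.5, 0.25)))
#' f[[1]]$magnitudes
#' @export
decode_stream <- function(text, n_expected = NULL) {
  dec <- frame_decoder()
  frames <- dec$feed(paste(text, collapse = ""))
  if (!is.null(n_expected) && !is.na(n_expected)) {
    frames <- lapply(frames, function(fr) {
      if (length(fr$magnitudes) != n_expected) {
        fr$valid <- FALSE
        fr$errors <- c(fr$errors,
                       sprintf("count mismatch: %d measurements, expected %d",
                               length(fr$magnitudes), n_expected))
      }
      fr
    })
  }
  frames
}

#' Convert decoded frames to a frames-by-channels matrix
#'
#' @param frames List of decoded frames (all with the same measurement
#'   count).
#' @return Numeric matrix, one row per frame.
#' @export
frames_to_matrix <- function(frames) {
  if (!length(frames)) return(matrix(numeric(0), nrow = 0, ncol = 0))
  lens <- vapply(frames, function(f) length(f$magnitudes), integer(1))
  if (length(unique(lens)) != 1)
    stop("frames have inconsistent measurement counts", call. = FALSE)
  do.call(rbind, lapply(frames, function(f) f$magnitudes))
}

#' Write / read frames as CSV (one row per frame)
#'
#' @param frames Matrix (frames x channels) or list of decoded frames.
#' @param path File path.
#' @export
write_frames_csv <- function(frames, path) {
  if (is.list(frames) && !is.matrix(frames)) frames <- frames_to_matrix(frames)
  m <- as.matrix(frames)
  colnames(m) <- sprintf("ch%03d", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(path) {
  as.matrix(utils::read.csv(path))
}
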