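# Demultiplexing of the free-run video: detector pixels identify the diode
# state of every frame; dark (reference) frames delimit illumination windows
# and provide the background; within a window, frames sharing the consensus
# code are combined by per-pixel maximum (so partially exposed rolling-shutter
# rows are overridden by fully lit ones) and the most recent dark frame is
# subtracted so constant stray light cancels.

#' Read the 12 detector pixels of a frame
#'
#' @param frame integer ADU matrix
#' @param layout a [detector_layout()]
#' @return numeric vector of 12 ADU levels in diode order
#' @export
read_detectors <- function(frame, layout) {
  st <- layout$sites
  if (any(st$row < 0 | st$row >= nrow(frame) |
          st$col < 0 | st$col >= ncol(frame))) {
    stop_invalid("detector site out of frame bounds (%d x %d frame)",
                 nrow(frame), ncol(frame))
  }
  as.numeric(frame[cbind(st$row + 1L, st$col + 1L)])
}

#' Classify a frame from its detector levels
#'
#' Bit `j` of the code is 1 iff `levels[j] - baseline[j] >= threshold`
#' (a level exactly at the threshold counts as lit). A frame whose bits are
#' all 0 is DARK. The per-site baseline defaults to 0, which is the plain
#' absolute-threshold rule; [extract()] passes the per-site minimum over
#' the video so that constant stray light cannot masquerade as lit
#' segments.
#'
#' @param levels numeric vector of 12 detector ADU levels
#' @param threshold detection level in ADU (default 20)
#' @param baseline per-site background level(s), scalar or length 12
#' @return 12-character binary code string; `"000000000000"` means DARK
#' @export
classify_frame <- function(levels, threshold = 20, baseline = 0) {
  if (length(levels) != 12L) stop_invalid("expected 12 detector levels")
  format_code(as.integer((levels - baseline) >= threshold))
}

#' Is a code the all-off (DARK) code?
#' @param code 12-character binary string
#' @return logical
#' @export
is_dark_code <- function(code) code == "000000000000"

#' Demultiplex a free-run video into per-pattern images
#'
#' Implements the post-processing extraction: (i) classify every frame from
#' its detector pixels (threshold rule, per-site minimum as baseline);
#' (ii) segment the stream into illumination windows delimited by DARK
#' frames; (iii) within a window, combine all frames sharing the window's
#' consensus code by per-pixel maximum (the maximum ensures the result
#' corresponds to full illumination during the exposure; rolling-shutter
#' transition frames whose code differs are excluded); (iv) subtract the
#' most recent preceding DARK frame pixelwise, clipped at 0, so constant
#' side illumination is eliminated; (v) emit one image, one acquisition
#' time (timestamp of the first contributing frame) and one code per
#' window. Windows before the first dark frame (no background available)
#' and the trailing window not closed by a dark frame are dropped with a
#' log line.
#'
#' The background is the darkest (minimum total intensity) frame of the
#' run of consecutive DARK frames immediately preceding the window, not
#' blindly the most recent one: frames whose exposure straddles the LED
#' switch edges read dark on the detector sites while their extreme rows
#' still carry some finger light, and taking the darkest frame of the
#' off-gap keeps that contamination out of the background estimate.
#'
#' @param video a `frame_sequence`
#' @param layout a [detector_layout()]; defaults to the layout the
#'   simulator attached to the video
#' @param threshold detection level in ADU (defaults to the layout's)
#' @return object of class `extraction_result`: list with `images` (8-bit
#'   integer matrices), `times` (s) and `codes` (12-char strings), all of
#'   equal length with strictly increasing times. The per-frame codes and
#'   drop counts are attached as attributes.
#' @export
extract <- function(video, layout = attr(video, "layout"),
                    threshold = layout$threshold) {
  if (is.null(layout)) stop_invalid("a detector_layout is required")
  nf <- n_frames(video)
  if (nf == 0L) stop_invalid("video is empty")
  st <- layout$sites
  levels <- matrix(0, nf, 12)
  for (j in 1:12) {
    levels[, j] <- video$frames[st$row[j] + 1L, st$col[j] + 1L, ]
  }
  baseline <- apply(levels, 2, min)
  bits <- sweep(levels, 2, baseline) >= threshold
  codes <- apply(bits, 1, function(b) format_code(as.integer(b)))
  dark <- !apply(bits, 1, any)
  if (!any(dark)) {
    stop_invalid("video contains no DARK frame: cannot establish background/delimiters")
  }
  if (all(dark)) {
    stop_invalid("video contains no illumination patterns (all frames DARK)")
  }
  frame_sums <- colSums(matrix(video$frames, ncol = nf))
  images <- list(); times <- numeric(0); out_codes <- character(0)
  B <- NULL
  dark_run <- integer(0)
  window <- integer(0)
  dropped_no_bg <- 0L; dropped_mixed <- 0L; dropped_open <- 0L
  finalize <- function(win) {
    if (length(win) == 0L) return(invisible(NULL))
    if (is.null(B)) {
      dropped_no_bg <<- dropped_no_bg + 1L
      vs_log("dropping window at frame %d: no preceding dark frame", win[1])
      return(invisible(NULL))
    }
    wcodes <- codes[win]
    sums <- rowSums(levels[win, , drop = FALSE])
    consensus <- wcodes[which.max(sums)]
    contrib <- win[wcodes == consensus]
    dropped_mixed <<- dropped_mixed + (length(win) - length(contrib))
    img <- video$frames[, , contrib[1]]
    for (k in contrib[-1]) img <- pmax(img, video$frames[, , k])
    img <- img - B
    img[img < 0L] <- 0L
    images[[length(images) + 1L]] <<- img
    times <<- c(times, video$timestamps[contrib[1]])
    out_codes <<- c(out_codes, consensus)
    invisible(NULL)
  }
  for (i in seq_len(nf)) {
    if (dark[i]) {
      finalize(window)
      window <- integer(0)
      dark_run <- c(dark_run, i)
      best <- dark_run[which.min(frame_sums[dark_run])]
      B <- video$frames[, , best]
    } else {
      window <- c(window, i)
      dark_run <- integer(0)
    }
  }
  if (length(window) > 0L) {
    dropped_open <- 1L
    vs_log("dropping trailing window of %d frames (not closed by a dark frame)",
           length(window))
  }
  structure(list(images = images, times = times, codes = out_codes),
            frame_codes = codes,
            baseline = baseline,
            threshold = threshold,
            dropped = c(no_background = dropped_no_bg,
                        mixed_frames = dropped_mixed,
                        open_window = dropped_open),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("extraction_result: %d images", length(x$images)))
  if (length(x$times) > 1) {
    cat(sprintf(", %.2f-%.2f s (%.1f /s)", min(x$times), max(x$times),
                length(x$times) / diff(range(x$times))))
  }
  cat("\n")
  tab <- table(x$codes)
  cat(sprintf("  %d distinct codes\n", length(tab)))
  invisible(x)
}

#' Number of extracted images
#' @param result an `extraction_result`
#' @return integer count
#' @export
n_extracted <- function(result) length(result$images)

#' Diode index of a single-diode code
#'
#' @param codes character vector of 12-bit codes
#' @return integer vector: 1-based diode index for single-diode codes,
#'   `NA` otherwise
#' @export
code_diode <- function(codes) {
  vapply(codes, function(code) {
    bits <- parse_code(code)
    if (sum(bits) == 1L) which(bits == 1L) else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Write extracted images in the processed-dataset layout
#'
#' Single-diode entries are written as `D<nn>_<t>.png` (1-based diode
#' index zero-padded to two digits; time in seconds with 2 decimals),
#' external-illumination entries as `DEXT_<t>.png`. Any other multi-diode
#' code is written as `P<code>_<t>.png` (an extension beyond the dataset
#' conventions, logged). The output directory name carries the suffix
#' `_processed`; a `manifest.csv` (filename, time, code) is written
#' alongside.
#'
#' @param result an `extraction_result`
#' @param out_dir output directory; `_processed` is appended when missing
#' @return invisibly, the manifest data.frame
#' @export
write_processed <- function(result, out_dir) {
  if (!grepl("_processed$", out_dir)) out_dir <- paste0(out_dir, "_processed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  diode <- code_diode(result$codes)
  fn <- character(length(result$codes))
  for (i in seq_along(fn)) {
    tlab <- sprintf("%.2f", result$times[i])
    fn[i] <- if (!is.na(diode[i])) {
      sprintf("D%02d_%s.png", diode[i], tlab)
    } else if (result$codes[i] == external_code()) {
      sprintf("DEXT_%s.png", tlab)
    } else {
      vs_log("multi-diode non-external code %s written with P-prefix",
             result$codes[i])
      sprintf("P%s_%s.png", result$codes[i], tlab)
    }
  }
  if (anyDuplicated(fn)) fn <- make.unique(fn, sep = "_")
  for (i in seq_along(fn)) {
    png::writePNG(result$images[[i]] / 255, file.path(out_dir, fn[i]))
  }
  manifest <- data.frame(filename = fn, time = result$times,
                         code = result$codes, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a processed-dataset directory back into an extraction result
#'
#' Uses `manifest.csv` when present; otherwise codes and times are parsed
#' from the `D<nn>_<t>.png` / `DEXT_<t>.png` filenames and entries sort
#' numerically by time.
#'
#' @param dir a `_processed` directory
#' @return an `extraction_result`
#' @export
read_processed <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    manifest <- utils::read.csv(mf, stringsAsFactors = FALSE,
                                colClasses = c(code = "character"))
  } else {
    files <- list.files(dir, pattern = "\\.png$")
    base <- sub("\\.png$", "", files)
    parts <- strsplit(base, "_")
    codes <- vapply(parts, function(p) {
      if (p[1] == "DEXT") {
        external_code()
      } else if (grepl("^D[0-9]{2}$", p[1])) {
        bits <- integer(12); bits[as.integer(sub("^D", "", p[1]))] <- 1L
        format_code(bits)
      } else {
        sub("^P", "", p[1])
      }
    }, character(1))
    times <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    manifest <- data.frame(filename = files, time = times, code = codes,
                           stringsAsFactors = FALSE)
    manifest <- manifest[order(manifest$time), ]
  }
  images <- lapply(manifest$filename, function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    m <- as.integer(round(img * 255))
    matrix(m, nrow(img))
  })
  structure(list(images = images, times = manifest$time,
                 codes = manifest$code),
            class = "extraction_result")
}
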