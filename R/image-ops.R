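# Device-side image pipeline: quality scoring, daily representative
# selection, and area-average downsizing for transmission.

#' Decode / encode PNG image bytes
#'
#' Images travel as raw PNG bytes; in memory they are numeric arrays in
#' [0, 1], either `height x width` (grayscale) or `height x width x 3`.
#'
#' @param bytes raw vector of PNG bytes.
#' @return `image_decode()`: a numeric array; `image_encode()`: raw bytes.
#' @export
image_decode <- function(bytes) {
  arr <- tryCatch(png::readPNG(bytes), error = function(e) {
    abort(paste0("undecodable image: ", conditionMessage(e)), class = "fm_scoring_error")
  })
  if (length(dim(arr)) == 3 && dim(arr)[3] == 4) arr <- arr[, , 1:3, drop = FALSE]
  arr
}

#' @rdname image_decode
#' @param img a numeric array in [0, 1].
#' @export
image_encode <- function(img) {
  png::writePNG(img)
}

to_gray <- function(img) {
  if (length(dim(img)) == 3) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    img
  }
}

#' Score an image for daily-representative selection
#'
#' Computes the three selection criteria: encoded file size (bytes), mean
#' grayscale intensity on a 0-255 scale, and clarity. Clarity is the
#' variance of a 3x3 discrete Laplacian of the grayscale image — a standard
#' no-reference sharpness proxy: a flat image scores 0 and blurring strictly
#' reduces the score.
#'
#' @param img raw PNG bytes, or a decoded numeric array in [0, 1] (then
#'   `file_size` is the size of its PNG encoding).
#' @return a one-row tibble `file_size, mean_intensity, clarity`.
#' @export
score_image <- function(img) {
  if (is.raw(img)) {
    bytes <- img
    arr <- image_decode(bytes)
  } else {
    arr <- img
    bytes <- image_encode(arr)
  }
  g <- to_gray(arr) * 255
  nr <- nrow(g); nc <- ncol(g)
  if (nr < 3 || nc < 3) {
    clarity <- 0
  } else {
    core <- g[2:(nr - 1), 2:(nc - 1)]
    lap <- g[1:(nr - 2), 2:(nc - 1)] + g[3:nr, 2:(nc - 1)] +
      g[2:(nr - 1), 1:(nc - 2)] + g[2:(nr - 1), 3:nc] - 4 * core
    clarity <- var(as.vector(lap))
  }
  tibble(file_size = length(bytes), mean_intensity = mean(g), clarity = clarity)
}

#' Selection configuration for the daily representative image
#'
#' File size and intensity act as hard gates (excluding truncated files and
#' black or blown-out frames); clarity is the objective maximized among the
#' survivors.
#'
#' @param min_file_size bytes; images smaller are filtered out. `NULL`
#'   (default) gates at 50% of the day's median file size.
#' @param intensity_low,intensity_high inclusive mean-intensity bounds on
#'   the 0-255 scale.
#' @param target_width,target_height transmission resolution of the chosen
#'   image (pixels).
#' @return a `selection_config` list.
#' @export
selection_config <- function(min_file_size = NULL, intensity_low = 40,
                             intensity_high = 215, target_width = 640,
                             target_height = 480) {
  if (intensity_low >= intensity_high) {
    abort("intensity_low must be below intensity_high", class = "fm_validation_error")
  }
  if (target_width <= 0 || target_height <= 0) {
    abort("target dimensions must be positive", class = "fm_validation_error")
  }
  structure(list(min_file_size = min_file_size, intensity_low = intensity_low,
                 intensity_high = intensity_high, target_width = target_width,
                 target_height = target_height),
            class = "selection_config")
}

#' Select the representative image of a day
#'
#' Filters out images failing the file-size or intensity gates, then
#' returns the maximum-clarity survivor; ties are broken by earliest
#' capture time. With no survivors (or no input) a zero-row tibble is
#' returned.
#'
#' @param images a tibble of same-day candidates with columns
#'   `capture_time`, `file_size`, `mean_intensity`, `clarity` (extra
#'   columns pass through).
#' @param config a [selection_config()].
#' @return the chosen one-row tibble, or a zero-row tibble.
#' @export
select_representative <- function(images, config = selection_config()) {
  if (nrow(images) == 0) return(images)
  min_fs <- config$min_file_size %||% (0.5 * stats::median(images$file_size))
  ok <- images$file_size >= min_fs &
    images$mean_intensity >= config$intensity_low &
    images$mean_intensity <= config$intensity_high
  survivors <- images[ok, , drop = FALSE]
  if (nrow(survivors) == 0) return(survivors)
  survivors <- arrange(survivors, dplyr::desc(.data$clarity), .data$capture_time)
  survivors[1, , drop = FALSE]
}

# 1D area-average resampling weights: m x n matrix whose row j averages
# input pixels overlapping output interval [j*s, (j+1)*s), s = n/m. Rows
# sum to 1 and each input pixel receives total weight s^-1, so the image
# mean is preserved exactly (before 8-bit quantization). Sparse above a
# size threshold; memoized since a device reuses one geometry all season.
.weights_cache <- new.env(parent = emptyenv())

resample_weights <- function(n, m) {
  key <- paste0(n, ":", m)
  cached <- .weights_cache[[key]]
  if (!is.null(cached)) return(cached)
  s <- n / m
  i_list <- vector("list", m); j_list <- vector("list", m); w_list <- vector("list", m)
  for (j in seq_len(m)) {
    lo <- (j - 1) * s
    hi <- j * s
    cells <- seq.int(floor(lo), min(ceiling(hi), n) - 1)
    ov <- pmin(hi, cells + 1) - pmax(lo, cells)
    keep <- ov > 1e-12
    i_list[[j]] <- rep.int(j, sum(keep))
    j_list[[j]] <- cells[keep] + 1L
    w_list[[j]] <- ov[keep] / s
  }
  i_idx <- unlist(i_list); j_idx <- unlist(j_list); w <- unlist(w_list)
  if (as.double(m) * n <= 1e5) {
    W <- matrix(0, m, n)
    W[cbind(i_idx, j_idx)] <- w
  } else {
    W <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = w, dims = c(m, n))
  }
  .weights_cache[[key]] <- W
  W
}

#' Downsize an image by area-average (block-mean) resampling
#'
#' Resamples a capture-resolution image to the transmission resolution
#' (default 640 x 480, from the native 2,592 x 1,944 — both 4:3). Each
#' output pixel is the area-weighted mean of the input pixels it covers, so
#' the global mean intensity is preserved to within one gray level and a
#' uniform image stays uniform. Inputs already at the target size are
#' returned unchanged.
#'
#' @param img raw PNG bytes or a decoded numeric array.
#' @param target_width,target_height output dimensions in pixels; the input
#'   aspect ratio must match.
#' @return same representation as the input (bytes in, bytes out).
#' @export
downsample_image <- function(img, target_width = 640, target_height = 480) {
  raw_in <- is.raw(img)
  arr <- if (raw_in) image_decode(img) else img
  d <- dim(arr)
  h <- d[1]; w <- d[2]
  if (w == target_width && h == target_height) return(img)
  if (w < target_width || h < target_height) {
    abort("input smaller than target resolution", class = "fm_validation_error")
  }
  if (abs(w / target_width - h / target_height) > 1e-9) {
    abort(sprintf("aspect-ratio mismatch: input %d:%d vs target %d:%d",
                  w, h, target_width, target_height),
          class = "fm_validation_error")
  }
  Wv <- resample_weights(h, target_height)
  Wh <- resample_weights(w, target_width)
  # two 1-D passes; sparse-times-dense on each side keeps this O(pixels)
  resample_plane <- function(p) {
    m1 <- as.matrix(Wv %*% p)
    t(as.matrix(Wh %*% t(m1)))
  }
  if (length(d) == 3) {
    out <- array(0, dim = c(target_height, target_width, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- resample_plane(arr[, , k])
  } else {
    out <- resample_plane(arr)
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  if (raw_in) image_encode(out) else out
}
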