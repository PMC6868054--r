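#' Synthetic binary image dataset
#'
#' Desk-scale stand-in for reduced, median-binarized visual datasets: each
#' class has a fixed random 12 x 12 binary prototype (balanced on/off);
#' samples are the prototype with i.i.d. pixel flips at \code{flipProb}.
#' Prototypes are redrawn (bounded retries) until all pairwise Hamming
#' distances are at least \code{minHamming} pixels, so classes are
#' separable by construction. Exactly reproducible from its parameters and
#' seed.
#'
#' @param nClasses number of classes (>= 2).
#' @param perClass samples per class (split 2:1 into train:test).
#' @param flipProb pixel flip probability in \code{[0, 0.5)}.
#' @param seed integer seed.
#' @param minHamming minimum pairwise prototype Hamming distance, pixels.
#' @return an [ImageDataset-class].
#' @export
#' @examples
#' ds <- makeSyntheticDataset(3, 30, flipProb = 0.05, seed = 1)
#' ds
makeSyntheticDataset <- function(nClasses = 3, perClass = 60,
                                 flipProb = 0.05, seed = 1L,
                                 minHamming = 20L) {
  stopifnot(nClasses >= 2, flipProb >= 0, flipProb < 0.5, perClass >= 1)
  withSeed(seed, {
    proto <- NULL
    for (try in 1:100) {
      proto <- t(vapply(seq_len(nClasses), function(cl)
        sample(rep(c(0L, 1L), 72)), integer(144)))
      dmin <- min(utils::combn(nClasses, 2, function(ij)
        sum(proto[ij[1], ] != proto[ij[2], ])))
      if (dmin >= minHamming) break
    }
    if (dmin < minHamming)
      stopf("could not draw prototypes %d pixels apart", minHamming)
    nTot <- nClasses * perClass
    labels <- rep(seq_len(nClasses), each = perClass)
    flips <- matrix(stats::runif(nTot * 144) < flipProb, nTot, 144)
    images <- (proto[labels, , drop = FALSE] + flips) %% 2L
    storage.mode(images) <- "integer"
    split <- rep(rep(c("train", "test"),
                     c(ceiling(2 * perClass / 3),
                       perClass - ceiling(2 * perClass / 3))), nClasses)
    new("ImageDataset", images = images, labels = as.integer(labels),
        split = split, nClasses = as.integer(nClasses), prototypes = proto)
  })
}

#' Reduce and binarize a grayscale image
#'
#' Converts a square grayscale image (e.g. 28 x 28) into a flat binary
#' 12 x 12 image: nearest-neighbor resampling per axis (source index of
#' output pixel \code{j} is \code{floor((j - 0.5) * m / 12) + 1} for an
#' m-pixel axis), then binarization around the per-image median gray value
#' with the strictly-greater-than convention (so a constant image maps to
#' all zeros).
#'
#' @param gray numeric square matrix of gray values.
#' @return integer vector of 144 binary pixels (row-major 12 x 12).
#' @export
#' @examples
#' img <- matrix(seq(0, 1, length.out = 784), 28, 28)
#' sum(reduceAndBinarize(img))
reduceAndBinarize <- function(gray) {
  if (!is.matrix(gray) || nrow(gray) != ncol(gray))
    stopf("input must be a square grayscale matrix")
  m <- nrow(gray)
  idx <- floor(((seq_len(12) - 0.5) * m) / 12) + 1L
  small <- gray[idx, idx]
  med <- stats::median(small)
  as.integer(t(small) > med)  # row-major flattening
}

#' Occlude image pixels
#'
#' Marks a fraction of pixels as receiving no input, following one of two
#' schemes: \code{"saltpepper"} picks a uniformly random pixel subset
#' without replacement; \code{"patch"} picks a contiguous rectangle (6 x 6
#' for the default 25\% of 144 pixels) at a seeded random position. If the
#' requested patch pixel count is not realizable as a rectangle, the nearest
#' realizable rectangle is used and reported via a message. Masked pixels
#' are tagged, not flipped.
#'
#' @param image integer vector of 144 binary pixels.
#' @param scheme \code{"saltpepper"} or \code{"patch"}.
#' @param fraction occluded fraction in (0, 1).
#' @param seed integer seed.
#' @return list with \code{image} (input, unchanged), \code{mask} (logical
#'   length-144 vector, \code{TRUE} = occluded) and \code{scheme}.
#' @export
#' @examples
#' occ <- occlude(rep(0L, 144), "patch", seed = 4)
#' sum(occ$mask)  # 36
occlude <- function(image, scheme = c("saltpepper", "patch"),
                    fraction = 0.25, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(length(image) == 144L)
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  k <- round(fraction * 144)
  mask <- logical(144)
  withSeed(seed, {
    if (scheme == "saltpepper") {
      mask[sample(144L, k)] <- TRUE
    } else {
      side <- round(sqrt(k))
      h <- side
      w <- round(k / side)
      if (h * w != k)
        message(sprintf("patch of %d pixels not realizable; using %d x %d = %d",
                        k, h, w, h * w))
      r0 <- sample(12L - h + 1L, 1L)
      c0 <- sample(12L - w + 1L, 1L)
      grid <- as.vector(outer(c0:(c0 + w - 1L), r0:(r0 + h - 1L),
                              function(cc, rr) (rr - 1L) * 12L + cc))
      mask[grid] <- TRUE
    }
  })
  list(image = image, mask = mask, scheme = scheme)
}
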