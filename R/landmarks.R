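#' Canonical facial landmark scheme
#'
#' The 22-point anthropometric landmark scheme used throughout the package:
#' 8 midline landmarks and 7 bilateral pairs. The set follows standard facial
#' anthropometry (Farkas nomenclature); `_L`/`_R` suffixes denote the
#' subject's left and right side. Any alternative scheme can be supplied to
#' [landmark_set()] as long as it comes with a left/right pairing involution.
#'
#' @return Character vector of the 22 canonical landmark names.
#' @export
#' @examples
#' canonical_landmark_names()
canonical_landmark_names <- function() {
  c(
    "glabella", "nasion", "pronasale", "subnasale",
    "labiale_superius", "labiale_inferius", "sublabiale", "gnathion",
    "exocanthion_L", "exocanthion_R",
    "endocanthion_L", "endocanthion_R",
    "alare_L", "alare_R",
    "cheilion_L", "cheilion_R",
    "zygion_L", "zygion_R",
    "tragion_L", "tragion_R",
    "gonion_L", "gonion_R"
  )
}

#' Left/right pairing for a landmark naming scheme
#'
#' Builds the involution sending each left-side name to its right-side partner
#' and each midline name to itself, based on `_L`/`_R` suffixes.
#'
#' @param names Character vector of landmark names.
#' @return Named character vector: `pairing[name]` is the mirror partner.
#' @export
landmark_pairing <- function(names = canonical_landmark_names()) {
  partner <- names
  is_l <- grepl("_L$", names)
  is_r <- grepl("_R$", names)
  partner[is_l] <- sub("_L$", "_R", names[is_l])
  partner[is_r] <- sub("_R$", "_L", names[is_r])
  missing <- setdiff(partner, names)
  if (length(missing) > 0) {
    abort(glue::glue(
      "landmark scheme is not closed under left/right pairing; missing: ",
      "{paste(missing, collapse = ', ')}"
    ))
  }
  setNames(partner, names)
}

#' Construct a landmark set
#'
#' @param points Numeric matrix with one row per landmark and columns x, y, z
#'   (mm); rownames are the landmark names.
#' @param pairing Named character vector mapping each name to its mirror
#'   partner (an involution); default derived from `_L`/`_R` suffixes.
#' @param scheme Expected landmark names. Set to `NULL` to accept any scheme.
#' @return An object of class `landmark_set`: the point matrix with a
#'   `pairing` attribute.
#' @export
landmark_set <- function(points,
                         pairing = landmark_pairing(rownames(points)),
                         scheme = canonical_landmark_names()) {
  points <- as.matrix(points)
  if (ncol(points) != 3) abort("landmark points must have 3 columns (x, y, z)")
  nm <- rownames(points)
  if (is.null(nm)) abort("landmark point matrix must have rownames (landmark names)")
  if (anyDuplicated(nm)) {
    abort(glue::glue("duplicate landmark name(s): ",
                     "{paste(unique(nm[duplicated(nm)]), collapse = ', ')}"))
  }
  if (!all(is.finite(points))) abort("landmark coordinates must be finite")
  if (!is.null(scheme)) {
    miss <- setdiff(scheme, nm)
    extra <- setdiff(nm, scheme)
    if (length(miss) > 0) {
      abort(glue::glue("missing landmark(s): {paste(miss, collapse = ', ')}"))
    }
    if (length(extra) > 0) {
      abort(glue::glue("unknown landmark(s): {paste(extra, collapse = ', ')}"))
    }
    points <- points[scheme, , drop = FALSE]
    nm <- scheme
  }
  # pairing must be an involution covering every name
  if (!setequal(names(pairing), nm)) abort("pairing must cover exactly the landmark names")
  if (!all(pairing[pairing[nm]] == nm)) abort("pairing must be an involution")
  colnames(points) <- c("x", "y", "z")
  structure(points, pairing = pairing[nm], class = c("landmark_set", "matrix", "array"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", nrow(x), " landmarks\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Euclidean distance between two named landmarks
#'
#' @param lms A [landmark_set()].
#' @param a,b Landmark names.
#' @return Distance in mm.
#' @export
#' @examples
#' lms <- landmark_set(
#'   matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE,
#'          dimnames = list(c("nasion", "pronasale"), NULL)),
#'   scheme = NULL
#' )
#' landmark_distance(lms, "nasion", "pronasale") # 5
landmark_distance <- function(lms, a, b) {
  nm <- rownames(lms)
  for (name in c(a, b)) {
    if (!name %in% nm) abort(glue::glue("unknown landmark name: {name}"))
  }
  sqrt(sum((lms[a, ] - lms[b, ])^2))
}

reflect_landmarks <- function(lms, plane_x = 0) {
  pairing <- attr(lms, "pairing")
  pts <- unclass(lms)
  pts[, 1] <- 2 * plane_x - pts[, 1]
  rownames(pts) <- unname(pairing[rownames(pts)])
  pts <- pts[names(pairing), , drop = FALSE]
  structure(pts, pairing = pairing, class = class(lms))
}
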