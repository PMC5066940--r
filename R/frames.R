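## Base and base-pair reference frames, and inter-pair step parameters.
##
## A frame is the least-squares superposition of the embedded standard base
## geometry onto the observed six-membered ring; twist is measured between
## successive pair frames about their mean normal (mid-step-triad
## convention, as in 3DNA). This local convention needs no global helix-axis
## fit and is robust for the qualitative question the analysis asks: is
## there a local twist dip at the lesion?

## parent table used for ring fitting (8OG shares the guanine ring)
.frame_parent <- c(DA = "DA", DG = "DG", DC = "DC", DT = "DT", `8OG` = "DG")

## Fit a frame to a named coordinate matrix of one residue.
base_frame_xyz <- function(m, code) {
  parent <- .frame_parent[[code]]
  if (is.null(parent)) stop("no standard base geometry for ", code,
                            call. = FALSE)
  std <- base_heavy_atoms(parent)[.FRAME_RING, , drop = FALSE]
  missing <- setdiff(.FRAME_RING, rownames(m))
  if (length(missing) > 0)
    stop("missing ring atom(s) for frame fit: ",
         paste(missing, collapse = ", "), call. = FALSE)
  obs <- m[.FRAME_RING, , drop = FALSE]
  fit <- kabsch(std, obs)
  list(origin = fit$t, axes = fit$R, fit_rmsd = fit$rmsd)
}

#' Standard reference frame of a base
#'
#' Superposes the embedded standard base geometry onto the observed
#' six-membered ring (N1, C2, N3, C4, C5, C6 for both purines and
#' pyrimidines; the O8 of 8-oxoguanine plays no role) and returns the fitted
#' frame: x toward the major groove, y toward the sugar, z along the base
#' normal.
#'
#' @param s a [dna_structure()].
#' @param model,chain,resi residue address.
#' @return List with `origin` (3-vector), `axes` (3x3 proper rotation whose
#'   columns are the frame axes), and `fit_rmsd` (angstrom).
#' @export
base_frame <- function(s, model = 1, chain = "A", resi) {
  res <- residues(s, chain)
  code <- res$resn[match(resi, res$resi)]
  if (is.na(code)) stop("no residue ", chain, ":", resi, call. = FALSE)
  base_frame_xyz(residue_xyz(s, chain, resi, model), code)
}

#' Mid-frame of a Watson-Crick pair
#'
#' Flips the complementary base's frame (180 degrees about its x-axis, the
#' antiparallel strand correction) and averages: origins arithmetically,
#' rotations by projection of the mean onto the nearest proper rotation
#' (equivalent to the quaternion geodesic midpoint for two frames).
#'
#' @param fa,fb frames as returned by [base_frame()]; `fb` belongs to the
#'   complementary, antiparallel base.
#' @return A frame (list with `origin`, `axes`).
#' @export
pair_frame <- function(fa, fb) {
  rb <- fb$axes %*% rot_x(180)
  list(origin = (fa$origin + fb$origin) / 2,
       axes = orthonormalize_rotation(fa$axes + rb))
}

#' Twist and rise between successive pair frames
#'
#' Twist is the rotation from the first pair frame to the next measured
#' about their mean z-axis; rise is the projection of the origin
#' displacement onto that axis.
#'
#' @param pf1,pf2 successive pair frames (5' to 3').
#' @return List with `twist` (degrees, in (-180, 180]) and `rise`
#'   (angstrom).
#' @export
step_twist <- function(pf1, pf2) {
  zm <- unitv(pf1$axes[, 3] + pf2$axes[, 3])
  proj <- function(v) {
    w <- v - sum(v * zm) * zm
    if (vnorm(w) < 1e-9) stop("degenerate frame geometry", call. = FALSE)
    unitv(w)
  }
  y1 <- proj(pf1$axes[, 2])
  y2 <- proj(pf2$axes[, 2])
  twist <- rad2deg(atan2(sum(cross3(y1, y2) * zm), sum(y1 * y2)))
  rise <- sum((pf2$origin - pf1$origin) * zm)
  list(twist = wrap180(twist), rise = rise)
}

#' Per-step twist/rise profile of a duplex
#'
#' @param s a [dna_structure()].
#' @param map a duplex map from [pair_duplex()].
#' @param model model index, or `NULL` for all models.
#' @return Data frame with columns `model`, `step`, `twist_deg`, `rise_A`;
#'   step k spans base pairs k and k+1.
#' @export
twist_profile <- function(s, map, model = NULL) {
  models <- if (is.null(model)) seq_len(n_models(s)) else model
  out <- lapply(models, function(m) {
    pf <- lapply(seq_len(nrow(map)), function(i) {
      fa <- base_frame(s, m, attr(map, "chain_a"), map$res_a[i])
      fb <- base_frame(s, m, attr(map, "chain_b"), map$res_b[i])
      pair_frame(fa, fb)
    })
    steps <- lapply(seq_len(nrow(map) - 1), function(k) {
      st <- step_twist(pf[[k]], pf[[k + 1]])
      data.frame(model = m, step = k, twist_deg = st$twist, rise_A = st$rise)
    })
    do.call(rbind, steps)
  })
  do.call(rbind, out)
}
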