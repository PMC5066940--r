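## Rigid-body superposition and ensemble RMSD statistics.

#' Least-squares superposition of two coordinate sets
#'
#' Kabsch (SVD) fit of `A` onto `B`: the returned proper rotation and
#' translation minimize the coordinate RMSD. Inputs are either bare n x 3
#' matrices in one-to-one row correspondence, or [dna_structure()] objects
#' (model 1 unless `model_a`/`model_b` are given) with a named atom
#' selection.
#'
#' @param A,B coordinate matrices or `dna_structure` objects.
#' @param selection `"all"`, `"all-heavy"`, `"backbone"` or a vector of atom
#'   names; used when the inputs are structures. Hydrogens are excluded from
#'   `"all-heavy"`.
#' @param model_a,model_b model indices for structure inputs.
#' @return List of class `superposition`: `R` (3x3, det +1), `t`
#'   (3-vector), `rmsd` (angstrom), `selection`, `n_atoms`.
#' @export
superpose <- function(A, B, selection = "all-heavy", model_a = 1,
                      model_b = 1) {
  pick <- function(s, model) {
    if (inherits(s, "dna_structure")) {
      idx <- select_atoms(s, selection)
      list(xyz = s$xyz[[model]][idx, , drop = FALSE],
           keys = atom_keys(s)[idx])
    } else {
      list(xyz = as.matrix(s), keys = NULL)
    }
  }
  a <- pick(A, model_a)
  b <- pick(B, model_b)
  if (!is.null(a$keys) && !is.null(b$keys) && !identical(a$keys, b$keys)) {
    um <- union(setdiff(a$keys, b$keys), setdiff(b$keys, a$keys))
    if (length(um) > 0)
      stop("correspondence error: unmatched atoms: ",
           paste(utils::head(um, 10), collapse = ", "),
           if (length(um) > 10) " ..." else "", call. = FALSE)
    ## same sets, different order: align B to A's order
    b$xyz <- b$xyz[match(a$keys, b$keys), , drop = FALSE]
  }
  if (nrow(a$xyz) != nrow(b$xyz))
    stop("correspondence error: selections differ in size (",
         nrow(a$xyz), " vs ", nrow(b$xyz), ")", call. = FALSE)
  fit <- kabsch(a$xyz, b$xyz)
  structure(list(R = fit$R, t = fit$t, rmsd = fit$rmsd,
                 selection = paste(selection, collapse = ","),
                 n_atoms = nrow(a$xyz)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd ", signif(x$rmsd, 4), " A over ", x$n_atoms,
      " atoms (", x$selection, ")\n", sep = "")
  invisible(x)
}

#' Pairwise RMSD matrix of an ensemble
#'
#' @param s a [dna_structure()] with at least 2 models.
#' @param selection atom selection, as in [superpose()].
#' @return List: `rmsd` (symmetric matrix), `max` and `mean` of the
#'   off-diagonal values, `selection`.
#' @export
pairwise_rmsd <- function(s, selection = "all-heavy") {
  nm <- n_models(s)
  if (nm < 2) stop("need at least 2 models", call. = FALSE)
  idx <- select_atoms(s, selection)
  mats <- lapply(s$xyz, function(m) m[idx, , drop = FALSE])
  rm <- matrix(0, nm, nm)
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      rm[i, j] <- rm[j, i] <- kabsch(mats[[i]], mats[[j]])$rmsd
    }
  }
  off <- rm[upper.tri(rm)]
  list(rmsd = rm, max = max(off), mean = mean(off),
       selection = paste(selection, collapse = ","))
}

#' Representative model of an ensemble
#'
#' `"mean-coordinates"` superposes every model onto the first and averages
#' the fitted coordinates (no force-field minimization is applied);
#' `"medoid"` returns the model minimizing the summed RMSD to all others.
#'
#' @param s a [dna_structure()].
#' @param mode `"medoid"` or `"mean-coordinates"`.
#' @param selection atom selection used for the fits.
#' @return A single-model [dna_structure()]; for `"medoid"` the chosen
#'   model index is attached as attribute `model`.
#' @export
representative <- function(s, mode = c("medoid", "mean-coordinates"),
                           selection = "all-heavy") {
  mode <- match.arg(mode)
  nm <- n_models(s)
  if (nm == 1) {
    out <- dna_structure(s$atoms, s$xyz[[1]], meta = s$meta)
    attr(out, "model") <- 1L
    return(out)
  }
  if (mode == "medoid") {
    pr <- pairwise_rmsd(s, selection)
    best <- which.min(rowSums(pr$rmsd))
    out <- dna_structure(s$atoms, s$xyz[[best]],
                         meta = paste0(s$meta, " | medoid model ", best))
    attr(out, "model") <- as.integer(best)
    out
  } else {
    idx <- select_atoms(s, selection)
    ref <- s$xyz[[1]]
    acc <- ref
    for (m in 2:nm) {
      fit <- kabsch(s$xyz[[m]][idx, , drop = FALSE],
                    ref[idx, , drop = FALSE])
      acc <- acc + sweep(s$xyz[[m]] %*% t(fit$R), 2, fit$t, "+")
    }
    dna_structure(s$atoms, acc / nm,
                  meta = paste0(s$meta, " | mean coordinates"))
  }
}

#' JSON ensemble RMSD report
#'
#' @param s a [dna_structure()].
#' @param path output file.
#' @param selection atom selection.
#' @return The report list, invisibly.
#' @export
write_rmsd_report <- function(s, path, selection = "all-heavy") {
  pr <- pairwise_rmsd(s, selection)
  rep <- list(selection = pr$selection, n_models = n_models(s),
              max_rmsd = pr$max, mean_rmsd = pr$mean, matrix = pr$rmsd)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
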