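## Idealized nucleotide geometry.
##
## Planar base heavy atoms are embedded as literal coordinate tables in the
## standard base reference frame (Tsukuba convention: x toward the major
## groove, y toward the sugar, z along the base normal; units angstrom).
## A Watson-Crick partner occupies the same frame after a 180 degree rotation
## about x. The sugar-phosphate moiety and all hydrogens are constructed once
## per base type by internal-coordinate chaining from canonical B-form
## torsions, so the whole template is reproducible from code.

.BASE_XY <- list(
  DA = rbind(
    `C1'` = c(-2.479, 5.346),
    N9 = c(-1.291, 4.498),
    C8 = c(0.024, 4.897),
    N7 = c(0.877, 3.902),
    C5 = c(0.071, 2.771),
    C6 = c(0.369, 1.398),
    N6 = c(1.611, 0.909),
    N1 = c(-0.668, 0.532),
    C2 = c(-1.912, 1.023),
    N3 = c(-2.320, 2.290),
    C4 = c(-1.267, 3.124)),
  DG = rbind(
    `C1'` = c(-2.477, 5.399),
    N9 = c(-1.289, 4.551),
    C8 = c(0.023, 4.962),
    N7 = c(0.870, 3.969),
    C5 = c(0.071, 2.833),
    C6 = c(0.424, 1.460),
    O6 = c(1.554, 0.955),
    N1 = c(-0.700, 0.641),
    C2 = c(-1.999, 1.087),
    N2 = c(-2.949, 0.139),
    N3 = c(-2.342, 2.364),
    C4 = c(-1.265, 3.177)),
  DC = rbind(
    `C1'` = c(-2.477, 5.402),
    N1 = c(-1.285, 4.542),
    C2 = c(-1.472, 3.158),
    O2 = c(-2.628, 2.709),
    N3 = c(-0.391, 2.344),
    C4 = c(0.837, 2.868),
    N4 = c(1.875, 2.027),
    C5 = c(1.056, 4.275),
    C6 = c(-0.023, 5.068)),
  DT = rbind(
    `C1'` = c(-2.481, 5.354),
    N1 = c(-1.284, 4.500),
    C2 = c(-1.462, 3.135),
    O2 = c(-2.562, 2.608),
    N3 = c(-0.298, 2.407),
    C4 = c(0.994, 2.897),
    O4 = c(1.944, 2.119),
    C5 = c(1.106, 4.338),
    C7 = c(2.466, 4.961),
    C6 = c(-0.024, 5.057))
)

## Six-membered ring used for reference-frame fitting (same six names for
## purines and pyrimidines; the O8 of 8-oxoguanine plays no part in fitting).
.FRAME_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

## Glycosidic nitrogen and the base atom defining chi for each code.
.GLYCOSIDIC <- list(
  DA = c("N9", "C4"), DG = c("N9", "C4"), `8OG` = c("N9", "C4"),
  DC = c("N1", "C2"), DT = c("N1", "C2"))

.COMPLEMENT <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG", `8OG` = "DC")

## Hydrogen-bond donor (heavy atom with attached H) and acceptor typing for
## the Watson-Crick and Hoogsteen edges of each base.
.HB_DONORS <- list(
  DA = c("N6"), DG = c("N1", "N2"), DC = c("N4"), DT = c("N3"),
  `8OG` = c("N1", "N2", "N7"))
.HB_ACCEPTORS <- list(
  DA = c("N1", "N3", "N7"), DG = c("O6", "N3", "N7"),
  DC = c("O2", "N3"), DT = c("O2", "O4"),
  `8OG` = c("O6", "N3", "O8"))

## Hydrogens covalently carried by each donor heavy atom (template naming).
.DONOR_H <- list(
  N6 = c("H61", "H62"), N1 = "H1", N2 = c("H21", "H22"),
  N4 = c("H41", "H42"), N3 = "H3", N7 = "H7")

base_codes <- function() names(.BASE_TEMPLATES)

element_of <- function(name) {
  stripped <- gsub("[0-9']", "", name)
  substr(stripped, 1, 1)
}

## --- base heavy atoms in the standard frame (z = 0 plane) ------------------

base_heavy_atoms <- function(code) {
  if (code == "8OG") {
    xy <- .BASE_XY[["DG"]]
    ## O8 sits on C8 along the former C8-H8 direction (in-plane), 1.23 A.
    c8 <- xy["C8", ]
    dir <- (c8 - (xy["N7", ] + xy["N9", ]) / 2)
    dir <- dir / sqrt(sum(dir^2))
    xy <- rbind(xy, O8 = c8 + 1.23 * dir)
  } else {
    xy <- .BASE_XY[[code]]
  }
  cbind(xy, z = 0)
}

## --- in-plane base hydrogens -----------------------------------------------

.ring_h_parent <- list(
  DA = list(H2 = c("C2", "N1", "N3"), H8 = c("C8", "N7", "N9")),
  DG = list(H8 = c("C8", "N7", "N9"), H1 = c("N1", "C2", "C6")),
  `8OG` = list(H1 = c("N1", "C2", "C6"), H7 = c("N7", "C5", "C8")),
  DC = list(H5 = c("C5", "C4", "C6"), H6 = c("C6", "C5", "N1")),
  DT = list(H3 = c("N3", "C2", "C4"), H6 = c("C6", "C5", "N1")))

.amino_h <- list(
  DA = list(N6 = c("C6", "H61", "H62")),
  DG = list(N2 = c("C2", "H21", "H22")),
  `8OG` = list(N2 = c("C2", "H21", "H22")),
  DC = list(N4 = c("C4", "H41", "H42")),
  DT = list())

base_hydrogens <- function(code, xyz) {
  out <- list()
  for (h in names(.ring_h_parent[[code]])) {
    spec <- .ring_h_parent[[code]][[h]]
    x <- xyz[spec[1], ]
    u1 <- unitv(x - xyz[spec[2], ])
    u2 <- unitv(x - xyz[spec[3], ])
    len <- if (element_of(spec[1]) == "N") 1.01 else 1.08
    out[[h]] <- x + len * unitv(u1 + u2)
  }
  for (n in names(.amino_h[[code]])) {
    spec <- .amino_h[[code]][[n]]
    np <- xyz[n, ]
    d <- unitv(np - xyz[spec[1], ])
    perp <- unitv(cross3(c(0, 0, 1), d))
    out[[spec[2]]] <- np + 1.01 * (d * cos(pi / 3) + perp * sin(pi / 3))
    out[[spec[3]]] <- np + 1.01 * (d * cos(pi / 3) - perp * sin(pi / 3))
  }
  if (code == "DT") {
    ## methyl hydrogens on C7
    c7 <- xyz["C7", ]
    axis <- unitv(c7 - xyz["C5", ])
    ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- unitv(cross3(axis, ref))
    v <- cross3(axis, u)
    for (k in 0:2) {
      phi <- 2 * pi * k / 3
      dirn <- cos(deg2rad(70.5)) * axis +
        sin(deg2rad(70.5)) * (cos(phi) * u + sin(phi) * v)
      out[[paste0("H7", k + 1)]] <- c7 + 1.09 * dirn
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

## --- sugar-phosphate construction ------------------------------------------

## Internal coordinates of the idealized B-form template (degrees). The
## values were fitted numerically so that stacking the template at 36 deg
## twist / 3.38 A rise yields a continuous strand with chemically sound
## junction geometry (O3'-P 1.60 A, C3'-O3'-P 119 deg, O3'-P-O5' 104 deg), a
## canonical BI backbone (eps 185, zeta 255, delta 135) and a C2'-endo ring
## phase (P about 162 deg). chi stays anti, gamma gauche+, beta trans.
.BB_IDEAL <- list(chi = 250.091, gamma = 52.253, beta = 165.675,
                  p_angle = 122.714, o3_angle = 126.565, o3_tor = 126.144,
                  P = 160.043, tau_m = 38)

nu_from_pucker <- function(P, tau_m) {
  j <- 0:4
  tau_m * cos(deg2rad(P + (j - 2) * 144))
}

methine_h <- function(x, n1, n2, n3) {
  x + 1.09 * unitv(-(unitv(n1 - x) + unitv(n2 - x) + unitv(n3 - x)))
}

methylene_h <- function(x, n1, n2) {
  u1 <- unitv(n1 - x)
  u2 <- unitv(n2 - x)
  b <- unitv(-(u1 + u2))
  p <- unitv(cross3(u1, u2))
  phi <- deg2rad(54.75)
  rbind(x + 1.09 * (b * cos(phi) + p * sin(phi)),
        x + 1.09 * (b * cos(phi) - p * sin(phi)))
}

## Build the complete nucleotide template for one base code: base + sugar +
## 5'-phosphate + hydrogens, in the standard base reference frame.
build_nt_template <- function(code) {
  xyz <- base_heavy_atoms(code)
  gly <- .GLYCOSIDIC[[code]]
  ngly <- xyz[gly[1], ]
  cref <- xyz[gly[2], ]
  c1p <- xyz["C1'", ]
  p <- .BB_IDEAL
  nu <- nu_from_pucker(p$P, p$tau_m)

  add <- function(name, pos) {
    xyz <<- rbind(xyz, matrix(pos, 1, 3, dimnames = list(name, NULL)))
  }
  add("O4'", place_atom(cref, ngly, c1p, 1.42, 108.2, p$chi))
  add("C2'", place_atom(cref, ngly, c1p, 1.52, 114.0, p$chi - 122))
  add("C3'", place_atom(xyz["O4'", ], c1p, xyz["C2'", ], 1.52, 102.6, nu[2]))
  add("C4'", place_atom(c1p, xyz["C2'", ], xyz["C3'", ], 1.52, 102.6, nu[3]))
  add("O3'", place_atom(c1p, xyz["C2'", ], xyz["C3'", ], 1.42, p$o3_angle,
                        nu[3] + p$o3_tor))
  add("C5'", place_atom(xyz["C2'", ], xyz["C3'", ], xyz["C4'", ], 1.51, 114.7,
                        nu[4] - 122))
  add("O5'", place_atom(xyz["C3'", ], xyz["C4'", ], xyz["C5'", ], 1.44, 110.2,
                        p$gamma))
  add("P", place_atom(xyz["C4'", ], xyz["C5'", ], xyz["O5'", ], 1.60,
                      p$p_angle, p$beta))
  add("OP1", place_atom(xyz["C5'", ], xyz["O5'", ], xyz["P", ], 1.49, 108.0,
                        60))
  add("OP2", place_atom(xyz["C5'", ], xyz["O5'", ], xyz["P", ], 1.49, 108.0,
                        180))

  add("H1'", methine_h(c1p, ngly, xyz["O4'", ], xyz["C2'", ]))
  h2 <- methylene_h(xyz["C2'", ], c1p, xyz["C3'", ])
  add("H2'", h2[1, ])
  add("H2''", h2[2, ])
  add("H3'", methine_h(xyz["C3'", ], xyz["C2'", ], xyz["C4'", ], xyz["O3'", ]))
  add("H4'", methine_h(xyz["C4'", ], xyz["C3'", ], xyz["O4'", ], xyz["C5'", ]))
  h5 <- methylene_h(xyz["C5'", ], xyz["C4'", ], xyz["O5'", ])
  add("H5'", h5[1, ])
  add("H5''", h5[2, ])

  bh <- base_hydrogens(code, xyz)
  if (!is.null(bh)) xyz <- rbind(xyz, bh)
  dimnames(xyz) <- list(rownames(xyz), c("x", "y", "z"))
  xyz
}

.template_cache <- new.env(parent = emptyenv())

nt_template <- function(code) {
  if (is.null(.template_cache[[code]]))
    .template_cache[[code]] <- build_nt_template(code)
  .template_cache[[code]]
}

#' Standard base reference geometry
#'
#' Returns the embedded idealized coordinates (angstrom) of a nucleotide in
#' the standard base reference frame, including the constructed
#' sugar-phosphate moiety and hydrogens.
#'
#' @param code residue code: one of `"DA"`, `"DC"`, `"DG"`, `"DT"`, `"8OG"`.
#' @return A named coordinate matrix (atoms x 3).
#' @export
standard_nucleotide <- function(code) {
  code <- toupper(code)
  if (!code %in% c("DA", "DC", "DG", "DT", "8OG"))
    stop("unknown residue code: ", code, call. = FALSE)
  nt_template(code)
}
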