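#' Build a coarse-grained peptide dimer
#'
#' Constructs a Calpha-level Go model of one of the two complexes of
#' the hairpin/monomer system, parameterised by the reported
#' hydrogen-bond counts:
#'
#' * `"HM"` — a 25-bead hairpin (Cys + HQKLVFFAED + YNGK turn +
#'   HQKLVFFAED, following the printed sequence) with the 11-bead
#'   monomer (CHQKLVFFAED) intercalated into the groove between its
#'   strands, stabilised by 5 inter-chain contacts plus 1 Lys-Asp
#'   salt-bridge contact at double well depth, and 3 intra-hairpin
#'   contacts.
#' * `"HH"` — two 25-bead hairpins associated sheet-to-sheet with 4
#'   inter-chain contacts (and 3 intra contacts per hairpin to keep
#'   each folded).
#'
#' Contact rest lengths equal the native pair distances, and the two
#' geometries are arranged so that all plain inter-chain contacts share
#' the same rest length (0.75 nm): the rupture-force comparison then
#' reflects the contact count and the salt bridge, not incidental
#' geometry. The built geometry is the energy minimum by construction.
#' The pulling groups are the first bead of each chain (the Calpha of
#' the N-terminal Cys of each molecule). In both models the pulled
#' termini enter the two contacting strands at opposite ends -- the
#' monomer binds the hairpin's first strand antiparallel -- so pulling
#' loads the contact ladder in shear (cooperatively) rather than
#' peeling it rung by rung.
#'
#' @param kind `"HM"` or `"HH"`.
#' @param contact_depth Native-contact well depth in kBT (the
#'   salt-bridge contact gets twice this).
#' @param bond_k Backbone bond stiffness in kBT/nm^2.
#' @param sigma_rep Soft-sphere repulsion diameter in nm for
#'   non-bonded, non-contact pairs.
#' @return Object of class `cg_model`: list with `coords` (n x 3 nm
#'   matrix), `chain` (integer per bead), `residue` (one-letter codes),
#'   `bonds` (tibble `i`, `j`, `r0`, `k`), `contacts` (tibble `i`, `j`,
#'   `r0`, `depth`, `class` in intra/inter/saltbridge), `pulling_groups`
#'   (bead indices), `sigma_rep`, `kind`.
#' @export
#' @examples
#' hm <- cg_dimer("HM")
#' table(hm$contacts$class)
cg_dimer <- function(kind = c("HM", "HH"), contact_depth = 6,
                     bond_k = 300, sigma_rep = 0.5) {
  kind <- match.arg(kind)
  stopifnot(contact_depth > 0, bond_k > 0, sigma_rep > 0)
  b <- 0.38  # Calpha-Calpha spacing, nm
  hairpin_seq <- strsplit("CHQKLVFFAEDYNGKHQKLVFFAED", "")[[1]]  # 25
  monomer_seq <- strsplit("CHQKLVFFAED", "")[[1]]                # 11

  hairpin_coords <- function(x0 = 0, sep = 1.2) {
    s <- sep / 1.2
    z <- rbind(
      cbind(x0, 0, (0:10) * b),                      # strand A, beads 1-11
      matrix(c(x0 + 0.10 * s, 0, 4.25,                # YNGK turn, 12-15
               x0 + 0.45 * s, 0, 4.55,
               x0 + 0.85 * s, 0, 4.50,
               x0 + 1.15 * s, 0, 4.20), 4, 3, byrow = TRUE),
      cbind(x0 + sep, 0, 3.8 - (0:9) * b))           # strand B, beads 16-25
    unname(z)
  }

  if (kind == "HM") {
    # wide hairpin (strand separation 1.5 nm) with the monomer
    # intercalated midway between the strands, antiparallel to strand A
    # so the two pulled N-termini sit at opposite ends of the contact
    # ladder (shear loading)
    co1 <- hairpin_coords(0, sep = 1.5)
    co2 <- cbind(0.75, 0, (10:0) * b)
    coords <- rbind(co1, co2)
    chain <- c(rep(1L, 25), rep(2L, 11))
    residue <- c(hairpin_seq, monomer_seq)
    m <- function(j) 25L + j
    # z-matched rungs between strand A and the antiparallel monomer
    inter <- rbind(c(2L, m(10L)), c(4L, m(8L)), c(6L, m(6L)),
                   c(8L, m(4L)), c(10L, m(2L)))
    salt <- c(4L, m(11L))  # hairpin Lys4 - monomer Asp11
    intra <- rbind(c(4L, 23L), c(7L, 20L), c(10L, 17L))
    contacts <- tibble(
      i = c(inter[, 1], salt[1], intra[, 1]),
      j = c(inter[, 2], salt[2], intra[, 2]),
      class = c(rep("inter", 5), "saltbridge", rep("intra", 3)))
  } else {
    co1 <- hairpin_coords(0)
    co2 <- hairpin_coords(1.95)  # facing strands 0.75 nm apart
    coords <- rbind(co1, co2)
    chain <- c(rep(1L, 25), rep(2L, 25))
    residue <- c(hairpin_seq, hairpin_seq)
    h2 <- function(i) 25L + i
    # chain 1 strand B faces chain 2 strand A; the pulled termini
    # (bead 1 of each chain) enter the facing strands at opposite ends
    inter <- rbind(c(17L, h2(10L)), c(19L, h2(8L)),
                   c(21L, h2(6L)), c(23L, h2(4L)))
    intra <- rbind(c(4L, 23L), c(7L, 20L), c(10L, 17L),
                   c(h2(4L), h2(23L)), c(h2(7L), h2(20L)),
                   c(h2(10L), h2(17L)))
    contacts <- tibble(
      i = c(inter[, 1], intra[, 1]),
      j = c(inter[, 2], intra[, 2]),
      class = c(rep("inter", 4), rep("intra", 6)))
  }

  dist_ij <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  contacts <- contacts |>
    mutate(r0 = map_dbl(seq_len(dplyr::n()),
                        function(k) dist_ij(.data$i[k], .data$j[k])),
           depth = ifelse(.data$class == "saltbridge",
                          2 * contact_depth, contact_depth)) |>
    select("i", "j", "r0", "depth", "class")

  bonds <- bind_rows(lapply(split(seq_along(chain), chain), function(idx) {
    tibble(i = idx[-length(idx)], j = idx[-1])
  })) |>
    mutate(r0 = map_dbl(seq_len(dplyr::n()),
                        function(k) dist_ij(.data$i[k], .data$j[k])),
           k = bond_k)

  structure(list(coords = coords, chain = chain, residue = residue,
                 bonds = bonds, contacts = contacts,
                 pulling_groups = c(1L, 26L), sigma_rep = sigma_rep,
                 kind = kind),
            class = "cg_model")
}

#' Assemble a coarse-grained model from parts
#'
#' Low-level constructor for custom bead models (e.g. small toy
#' systems for sampler diagnostics). [cg_dimer()] is the high-level
#' builder for the study's two complexes.
#'
#' @param coords n x 3 matrix of bead positions in nm.
#' @param chain Integer chain id per bead.
#' @param bonds Tibble with `i`, `j`, `r0`, `k` (may have zero rows).
#' @param contacts Tibble with `i`, `j`, `r0`, `depth`, `class` (may
#'   have zero rows).
#' @param pulling_groups Length-2 bead indices on distinct chains.
#' @param sigma_rep Soft-sphere diameter in nm.
#' @param residue Optional one-letter residue codes (defaults to "A").
#' @param kind Label.
#' @return A `cg_model`.
#' @export
cg_model <- function(coords, chain, bonds = NULL, contacts = NULL,
                     pulling_groups, sigma_rep = 0.5, residue = NULL,
                     kind = "custom") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, length(chain) == nrow(coords),
            length(pulling_groups) == 2)
  if (chain[pulling_groups[1]] == chain[pulling_groups[2]]) {
    abort("pulling groups must sit on distinct chains.",
          class = "smc_param_error")
  }
  empty_bonds <- tibble(i = integer(), j = integer(), r0 = numeric(),
                        k = numeric())
  empty_contacts <- tibble(i = integer(), j = integer(), r0 = numeric(),
                           depth = numeric(), class = character())
  structure(list(coords = coords, chain = as.integer(chain),
                 residue = residue %||% rep("A", nrow(coords)),
                 bonds = bonds %||% empty_bonds,
                 contacts = contacts %||% empty_contacts,
                 pulling_groups = as.integer(pulling_groups),
                 sigma_rep = sigma_rep, kind = kind),
            class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat(sprintf(
    "Coarse-grained %s dimer: %d beads in %d chains, %d contacts (%d inter-chain)\n",
    x$kind, nrow(x$coords), length(unique(x$chain)), nrow(x$contacts),
    sum(x$contacts$class != "intra")))
  invisible(x)
}
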