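## Ligand chemistry: SMILES parsing (via OpenBabel through ChemmineR), bond
## graph + Laplacian construction, a deterministic reference conformer, and
## SDF ligand I/O.

## Characters legal in (a generous superset of) SMILES; used to name the
## offending token before OpenBabel sees the string.
.SMILES_CHARS <- c(LETTERS, letters, as.character(0:9),
                   "(", ")", "[", "]", "=", "#", "-", "+", ".", "/", "\\",
                   "@", "%", ":", "*")

#' Build the graph Laplacian L = D - A of a ligand bond graph
#'
#' @param graph a [LigandGraph-class] (its topology slots are used).
#' @return the Laplacian matrix; symmetric, rows summing to zero, positive
#'   semi-definite with one zero eigenvalue per connected fragment.
#' @examples
#' g <- parseSmiles("CC")
#' buildLaplacian(g)   # matrix(c(1, -1, -1, 1), 2)
#' @export
buildLaplacian <- function(graph) {
  n <- if (is(graph, "LigandGraph")) nAtoms(graph) else graph$n
  bonds <- if (is(graph, "LigandGraph")) graph@bonds else graph$bonds
  A <- matrix(0, n, n)
  if (nrow(bonds) > 0) {
    A[cbind(bonds[, 1], bonds[, 2])] <- 1
    A[cbind(bonds[, 2], bonds[, 1])] <- 1
  }
  diag(rowSums(A), n) - A
}

## Internal constructor from topology; computes A, D, L, fragments, conformer.
.makeLigandGraph <- function(elements, bonds, smiles = "", seed = 0L) {
  n <- length(elements)
  if (n == 0L) stop_input("ligand has zero heavy atoms")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    bonds <- unique(bonds)
  }
  A <- matrix(0, n, n)
  if (nrow(bonds) > 0) {
    A[cbind(bonds[, 1], bonds[, 2])] <- 1
    A[cbind(bonds[, 2], bonds[, 1])] <- 1
  }
  D <- diag(rowSums(A), n)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  frag <- as.integer(igraph::components(g)$membership)
  obj <- new("LigandGraph", elements = elements, bonds = bonds,
             fragmentId = frag, adjacency = A, degree = D, laplacian = D - A,
             refCoords = matrix(0, n, 3), smiles = smiles)
  obj@refCoords <- .embedConformer(obj, seed)
  validObject(obj)
  obj
}

#' Parse a SMILES string into a ligand bond graph
#'
#' Parses (possibly multi-fragment, "."-separated) SMILES through OpenBabel,
#' strips hydrogens, labels connected components and embeds a deterministic
#' reference 3D conformer used for bond-length bookkeeping. Aromatic bonds
#' count as single edges of the unweighted bond graph.
#'
#' @param smiles a SMILES string.
#' @param seed integer seed for the deterministic conformer embedding.
#' @return a [LigandGraph-class].
#' @examples
#' parseSmiles("CC.O")        # ethane + water: 3 atoms, 1 bond, 2 fragments
#' @export
parseSmiles <- function(smiles, seed = 0L) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop_input("smiles must be a non-empty string")
  chars <- strsplit(smiles, "")[[1]]
  bad <- setdiff(chars, .SMILES_CHARS)
  if (length(bad))
    stop_input("unparsable SMILES '%s': invalid token '%s'", smiles, bad[1])
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop_input("unparsable SMILES '%s'", smiles)
  )
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(bb) || nrow(bb) == 0) matrix(integer(0), 0, 2) else
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  ## strip hydrogens (explicit [H] atoms)
  heavy <- which(elements != "H")
  if (length(heavy) == 0L) stop_input("SMILES '%s' has zero heavy atoms", smiles)
  remap <- integer(length(elements)); remap[heavy] <- seq_along(heavy)
  if (nrow(bonds) > 0) {
    keep <- bonds[, 1] %in% heavy & bonds[, 2] %in% heavy
    bonds <- matrix(remap[bonds[keep, , drop = FALSE]], ncol = 2)
  }
  .makeLigandGraph(elements[heavy], bonds, smiles = smiles, seed = seed)
}

## Deterministic conformer embedding: per fragment, classical MDS on
## shortest-path distances scaled to a 1.5 A bond length, a seeded symmetry-
## breaking jitter, then gradient refinement of a bond-spring + soft-repulsion
## energy. Fragments are laid out side by side along x.
.embedConformer <- function(graph, seed, bondLength = 1.5, nIter = 200L) {
  n <- nAtoms(graph)
  coords <- matrix(0, n, 3)
  g <- igraph::graph_from_adjacency_matrix(graph@adjacency, mode = "undirected")
  offset <- 0
  with_seed_(derive_seed(seed, "conformer"), {
    for (f in sort(unique(graph@fragmentId))) {
      idx <- which(graph@fragmentId == f)
      m <- length(idx)
      if (m == 1L) {
        xyz <- matrix(0, 1, 3)
      } else {
        sp <- igraph::distances(igraph::induced_subgraph(g, idx))
        mds <- suppressWarnings(stats::cmdscale(sp * bondLength,
                                                k = min(3L, m - 1L)))
        xyz <- matrix(0, m, 3)
        xyz[, seq_len(ncol(mds))] <- mds
        xyz <- xyz + matrix(stats::rnorm(m * 3, sd = 0.05), m, 3)
        bsub <- graph@bonds[graph@bonds[, 1] %in% idx, , drop = FALSE]
        b1 <- match(bsub[, 1], idx); b2 <- match(bsub[, 2], idx)
        for (it in seq_len(nIter)) {
          grad <- matrix(0, m, 3)
          if (length(b1)) {
            dv <- xyz[b1, , drop = FALSE] - xyz[b2, , drop = FALSE]
            dl <- sqrt(rowSums(dv^2)); dl[dl < 1e-8] <- 1e-8
            gb <- dv * (2 * (dl - bondLength) / dl)
            for (e in seq_along(b1)) {
              grad[b1[e], ] <- grad[b1[e], ] + gb[e, ]
              grad[b2[e], ] <- grad[b2[e], ] - gb[e, ]
            }
          }
          ## soft repulsion between non-bonded atoms closer than 2.2 A
          dm <- cross_dist(xyz, xyz); diag(dm) <- Inf
          if (length(b1)) dm[cbind(c(b1, b2), c(b2, b1))] <- Inf
          close <- which(dm < 2.2, arr.ind = TRUE)
          if (nrow(close)) {
            for (e in seq_len(nrow(close))) {
              i <- close[e, 1]; j <- close[e, 2]
              dv <- xyz[i, ] - xyz[j, ]; dl <- max(sqrt(sum(dv^2)), 1e-8)
              grad[i, ] <- grad[i, ] - dv * (2 * (2.2 - dl) / dl)
            }
          }
          xyz <- xyz - 0.05 * grad
        }
        xyz <- sweep(xyz, 2, colMeans(xyz))
      }
      ext <- if (m > 1) max(cross_dist(xyz, xyz)) else 0
      xyz[, 1] <- xyz[, 1] + offset + ext / 2
      offset <- offset + ext + 3
      coords[idx, ] <- xyz
    }
  })
  coords
}

#' Read a ligand from an SDF (V2000) file
#'
#' @param path SDF file path (first molecule is used).
#' @param seed seed for the reference conformer embedding.
#' @return list with `graph` (a [LigandGraph-class]) and `coords` (the
#'   coordinates stored in the file).
#' @export
readLigandSDF <- function(path, seed = 0L) {
  if (!file.exists(path)) stop_input("no such SDF file: %s", path)
  sdf <- ChemmineR::read.SDFset(path)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  bonds <- if (is.null(bb) || nrow(bb) == 0) matrix(integer(0), 0, 2) else
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  heavy <- which(elements != "H")
  if (!length(heavy)) stop_input("SDF %s has zero heavy atoms", path)
  remap <- integer(length(elements)); remap[heavy] <- seq_along(heavy)
  if (nrow(bonds) > 0) {
    keep <- bonds[, 1] %in% heavy & bonds[, 2] %in% heavy
    bonds <- matrix(remap[bonds[keep, , drop = FALSE]], ncol = 2)
  }
  list(graph = .makeLigandGraph(elements[heavy], bonds, seed = seed),
       coords = coords[heavy, , drop = FALSE])
}

#' Write a ligand as an SDF (V2000) file
#'
#' @param graph a [LigandGraph-class].
#' @param coords atom coordinates (atoms x 3); defaults to the reference
#'   conformer.
#' @param path output path.
#' @param name molecule name written to the header.
#' @export
writeLigandSDF <- function(graph, coords = graph@refCoords, path,
                           name = "ligand") {
  n <- nAtoms(graph)
  if (nrow(coords) != n) stop_input("coords inconsistent with ligand graph")
  nb <- nrow(graph@bonds)
  lines <- c(
    name, "  cfmdock", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], graph@elements)
  )
  if (nb > 0)
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              graph@bonds[, 1], graph@bonds[, 2], rep(1L, nb)))
  lines <- c(lines, "M  END", "$$$$")
  atomic_write_lines(lines, path)
}
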