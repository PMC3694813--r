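# classification cutoffs (angstroms) for inter-molecular residue contacts
.defaultCutoffs <- c(hbond = 4.0, polar = 3.5, nonpolar = 4.5,
                     neighbor = 5.0)

#' Classify inter-molecular residue contacts at an interface
#'
#' For every residue pair with any inter-group heavy-atom pair within the
#' nearest-neighbor cutoff (5 A), one record is emitted carrying the minimal
#' atom-pair distance and a contact classification:
#' \describe{
#'   \item{hbond_range}{an N/O - N/O pair within 4 A (hydrogen-bond-capable
#'     polar contact; donor/acceptor chemistry approximated by element type)}
#'   \item{polar}{an N/O/S - N/O/S pair within 3.5 A (other polar contact)}
#'   \item{nonpolar}{a C - C pair within 4.5 A (van der Waals/hydrophobic)}
#'   \item{neighbor}{any heavy-atom pair within 5 A}
#' }
#' A pair may satisfy several classes; the reported `contact_class` is the
#' most specific (smallest satisfied cutoff) and all satisfied classes are
#' listed in `classes`. Hydrogens are ignored; distances always use heavy
#' atoms.
#'
#' @param structure a one-frame [Trajectory-class]
#' @param groupA,groupB disjoint [AtomSelection-class] groups (the two
#'   molecules).
#' @param cutoffs named numeric vector with entries `hbond`, `polar`,
#'   `nonpolar`, `neighbor` (defaults 4.0, 3.5, 4.5, 5.0 A).
#' @return data.frame with one row per contacting residue pair: `chain_a`,
#'   `resid_a`, `resname_a`, `chain_b`, `resid_b`, `resname_b`,
#'   `min_distance`, `atom_a`, `atom_b`, `contact_class`, `classes`.
#' @export
interfaceContacts <- function(structure, groupA, groupB,
                              cutoffs = .defaultCutoffs) {
    stopifnot(is(structure, "Trajectory"))
    if (nFrames(structure) != 1L)
        stop("contact analysis expects a single structure (one frame)")
    co <- .frame(structure, 1L)
    at <- structure@atoms
    ia <- .resolveIndices(groupA, nAtoms(structure))
    ib <- .resolveIndices(groupB, nAtoms(structure))
    if (length(intersect(ia, ib)))
        stop("contact groups overlap; selections must be disjoint")
    miss <- setdiff(names(.defaultCutoffs), names(cutoffs))
    if (length(miss))
        stop("cutoffs must name: ", paste(miss, collapse = ", "))
    heavy <- toupper(at$elem) != "H"
    ia <- ia[heavy[ia]]; ib <- ib[heavy[ib]]
    if (!length(ia) || !length(ib)) stop("a contact group has no heavy atoms")
    A <- co[ia, , drop = FALSE]; B <- co[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
          outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
    D <- sqrt(pmax(d2, 0))
    within <- which(D <= cutoffs[["neighbor"]], arr.ind = TRUE)
    if (nrow(within) == 0L) return(.emptyContacts())
    ea <- toupper(at$elem[ia]); eb <- toupper(at$elem[ib])
    keyA <- paste(at$chain[ia], at$resid[ia], sep = ":")
    keyB <- paste(at$chain[ib], at$resid[ib], sep = ":")
    pairKey <- paste(keyA[within[, 1]], keyB[within[, 2]], sep = "|")
    recs <- lapply(split(seq_len(nrow(within)), pairKey), function(rows) {
        w <- within[rows, , drop = FALSE]
        d <- D[w]
        NO <- c("N", "O"); NOS <- c("N", "O", "S")
        pa <- ea[w[, 1]]; pb <- eb[w[, 2]]
        sat <- c(
            polar = any(pa %in% NOS & pb %in% NOS & d <= cutoffs[["polar"]]),
            hbond_range = any(pa %in% NO & pb %in% NO &
                              d <= cutoffs[["hbond"]]),
            nonpolar = any(pa == "C" & pb == "C" &
                           d <= cutoffs[["nonpolar"]]),
            neighbor = TRUE)
        # most specific class = smallest satisfied cutoff
        cutoff_of <- c(polar = cutoffs[["polar"]],
                       hbond_range = cutoffs[["hbond"]],
                       nonpolar = cutoffs[["nonpolar"]],
                       neighbor = cutoffs[["neighbor"]])
        satisfied <- names(sat)[sat]
        primary <- satisfied[which.min(cutoff_of[satisfied])]
        best <- rows[which.min(d)]
        wa <- ia[within[best, 1]]; wb <- ib[within[best, 2]]
        data.frame(chain_a = at$chain[wa], resid_a = at$resid[wa],
                   resname_a = at$resname[wa], chain_b = at$chain[wb],
                   resid_b = at$resid[wb], resname_b = at$resname[wb],
                   min_distance = min(d), atom_a = at$name[wa],
                   atom_b = at$name[wb], contact_class = primary,
                   classes = paste(satisfied, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    out <- out[order(out$chain_a, out$resid_a, out$chain_b, out$resid_b), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

.emptyContacts <- function() {
    data.frame(chain_a = character(0), resid_a = integer(0),
               resname_a = character(0), chain_b = character(0),
               resid_b = integer(0), resname_b = character(0),
               min_distance = numeric(0), atom_a = character(0),
               atom_b = character(0), contact_class = character(0),
               classes = character(0), stringsAsFactors = FALSE)
}

#' Compare two interface contact lists
#'
#' Set operations on residue-pair keys (chain:resid of both partners), used
#' to ask whether two binding modes engage overlapping receptor surfaces.
#'
#' @param contactsA,contactsB data.frames from [interfaceContacts()].
#' @return list with `shared` (merged data.frame, classes from both lists),
#'   `uniqueA`, `uniqueB`, and `n_shared`.
#' @export
compareInterfaces <- function(contactsA, contactsB) {
    keyOf <- function(x) paste(x$chain_a, x$resid_a, x$chain_b, x$resid_b,
                               sep = ":")
    ka <- keyOf(contactsA); kb <- keyOf(contactsB)
    shared_keys <- intersect(ka, kb)
    sa <- contactsA[match(shared_keys, ka), , drop = FALSE]
    sb <- contactsB[match(shared_keys, kb), , drop = FALSE]
    shared <- if (length(shared_keys)) {
        cbind(sa[, c("chain_a", "resid_a", "resname_a", "chain_b",
                     "resid_b", "resname_b")],
              data.frame(class_a = sa$contact_class,
                         class_b = sb$contact_class,
                         min_distance_a = sa$min_distance,
                         min_distance_b = sb$min_distance))
    } else NULL
    list(shared = shared,
         uniqueA = contactsA[!(ka %in% shared_keys), , drop = FALSE],
         uniqueB = contactsB[!(kb %in% shared_keys), , drop = FALSE],
         n_shared = length(shared_keys))
}

#' Write contact records as TSV
#'
#' @param contacts data.frame from [interfaceContacts()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
writeContacts <- function(contacts, path) {
    utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
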