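#' Read a (possibly multi-model) PDB file into a Trajectory
#'
#' Fixed-column PDB parsing is delegated to [bio3d::read.pdb()]; each MODEL
#' becomes one trajectory frame. The atom table carries chain, author residue
#' number, residue name, atom name, element and the B-factor column
#' (columns 61-66).
#'
#' @param path PDB file path.
#' @param modelPolicy `"all"` (one frame per MODEL, default) or `"first"`.
#' @return a [Trajectory-class]
#' @examples
#' spec <- makeBlockSystem(nBlocks = 2, atomsPerBlock = 5, hingeAtoms = 2,
#'                         seed = 1)
#' traj <- generateENMTrajectory(spec, nFrames = 3)
#' f <- tempfile(fileext = ".pdb")
#' writePDB(traj, f)
#' nFrames(readPDB(f))
#' @export
readPDB <- function(path, modelPolicy = c("all", "first")) {
    modelPolicy <- match.arg(modelPolicy)
    if (!file.exists(path)) stop("PDB file not found: ", path)
    .validatePDBLines(path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    if (nrow(at) == 0L) stop("no atoms found in ", path)
    if (any(!is.na(at$insert) & nzchar(at$insert)))
        stop("insertion codes are not supported (found in ", path, ")")
    elem <- at$elesy
    guess <- toupper(substr(gsub("[0-9']", "", at$elety), 1L, 1L))
    elem <- ifelse(is.na(elem) | !nzchar(elem), guess, elem)
    atoms <- data.frame(chain = ifelse(is.na(at$chain), "", at$chain),
                        resid = at$resno, resname = at$resid,
                        name = at$elety, elem = elem, bfactor = at$b,
                        stringsAsFactors = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    if (modelPolicy == "first") xyz <- xyz[1L, , drop = FALSE]
    traj <- .trajectoryFromXYZ(xyz, atoms)
    .logInfo("read %s: %d frame(s), %d atoms", basename(path),
             nFrames(traj), nAtoms(traj))
    traj
}

# light pre-validation so malformed coordinate records are reported with a
# line number (the downstream parser is tolerant and would mangle them)
.validatePDBLines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    rec <- grepl("^(ATOM  |HETATM)", lines)
    if (!any(rec)) stop("no ATOM/HETATM records in ", path)
    for (ln in which(rec)) {
        l <- lines[ln]
        if (nchar(l) < 54L)
            stop(sprintf("malformed ATOM/HETATM record at line %d of %s: too short",
                         ln, path))
        for (cols in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
            fld <- substr(l, cols[1], cols[2])
            if (is.na(suppressWarnings(as.numeric(fld))))
                stop(sprintf(
                    "malformed ATOM/HETATM record at line %d of %s: non-numeric coordinate field '%s'",
                    ln, path, fld))
        }
    }
    invisible(TRUE)
}

.trajectoryFromXYZ <- function(xyz, atoms, frameInterval = NA_real_) {
    nF <- nrow(xyz); nA <- ncol(xyz) %/% 3L
    if (ncol(xyz) != 3L * nrow(atoms))
        stop(sprintf("coordinate columns (%d) disagree with atom table (%d atoms)",
                     ncol(xyz), nrow(atoms)))
    co <- array(0, dim = c(nF, nA, 3L))
    for (d in 1:3) co[, , d] <- xyz[, seq(d, by = 3L, length.out = nA),
                                    drop = FALSE]
    new("Trajectory", coords = co, atoms = atoms,
        frameInterval = frameInterval)
}

.xyzFromTrajectory <- function(traj) {
    nF <- nFrames(traj); nA <- nAtoms(traj)
    xyz <- matrix(0, nF, 3L * nA)
    for (d in 1:3) xyz[, seq(d, by = 3L, length.out = nA)] <- traj@coords[, , d]
    xyz
}

#' Write a Trajectory as a (multi-model) PDB file
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writePDB <- function(traj, path) {
    at <- traj@atoms
    b <- ifelse(is.na(at$bfactor), 0, at$bfactor)
    chain <- ifelse(nzchar(at$chain), at$chain, " ")
    bio3d::write.pdb(file = path, xyz = .xyzFromTrajectory(traj),
                     resno = at$resid, resid = at$resname, elety = at$name,
                     chain = chain, b = b, elesy = at$elem)
    invisible(path)
}

#' Read a binary or text trajectory with a companion topology
#'
#' Supported trajectory formats: CHARMM/NAMD DCD (via [bio3d::read.dcd()];
#' coordinates are angstroms), multi-model PDB, and the package's plain-text
#' fixture format (`.crd`/`.txt`, see [writeCoordsText()]). The topology is a
#' PDB file supplying the atom table.
#'
#' @param topology PDB file path (atom table source).
#' @param traj trajectory file path.
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(topology, traj) {
    top <- readPDB(topology, modelPolicy = "first")
    ext <- tolower(tools::file_ext(traj))
    xyz <- switch(ext,
        dcd = bio3d::read.dcd(traj, verbose = FALSE),
        pdb = .xyzFromTrajectory(readPDB(traj, modelPolicy = "all")),
        crd = ,
        txt = .readCoordsXYZ(traj),
        stop("unsupported trajectory format '", ext,
             "'; supported formats: dcd, pdb, crd, txt"))
    xyz <- unclass(xyz)
    if (ncol(xyz) != 3L * nAtoms(top))
        stop(sprintf(
            "atom-count mismatch: topology has %d atoms, trajectory has %d",
            nAtoms(top), ncol(xyz) %/% 3L))
    out <- .trajectoryFromXYZ(xyz, top@atoms)
    .logInfo("read %s: %d frame(s), %d atoms", basename(traj),
             nFrames(out), nAtoms(out))
    out
}

#' Write a Trajectory in CHARMM DCD format
#'
#' Minimal single-precision CHARMM DCD writer (no unit cell). Readable by
#' [bio3d::read.dcd()] and standard MD tooling.
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeDCD <- function(traj, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    nF <- nFrames(traj); nA <- nAtoms(traj)
    rec <- function(payload_writer, nbytes) {
        writeBin(as.integer(nbytes), con, size = 4L)
        payload_writer()
        writeBin(as.integer(nbytes), con, size = 4L)
    }
    icntrl <- integer(20L)
    icntrl[1] <- nF; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nF
    icntrl[20] <- 24L
    rec(function() {
        writeChar("CORD", con, nchars = 4L, eos = NULL)
        writeBin(icntrl, con, size = 4L)
    }, 84L)
    title <- formatC("Written by ecdyn::writeDCD", width = -80L)
    rec(function() {
        writeBin(1L, con, size = 4L)
        writeChar(title, con, nchars = 80L, eos = NULL)
    }, 84L)
    rec(function() writeBin(as.integer(nA), con, size = 4L), 4L)
    for (f in seq_len(nF)) {
        for (d in 1:3) {
            rec(function() writeBin(as.numeric(traj@coords[f, , d]), con,
                                    size = 4L), 4L * nA)
        }
    }
    invisible(path)
}

#' Plain-text coordinate fixtures
#'
#' A tiny whitespace-delimited format for test fixtures: a header line
#' `# ecdyn-coords <n_frames> <n_atoms>` followed by `n_frames * n_atoms`
#' rows of `x y z` (angstroms), frames in order.
#'
#' @param traj a [Trajectory-class]
#' @param path file path
#' @return `writeCoordsText`: `path` invisibly; `readCoordsText`: a
#'   [Trajectory-class] (generic atom table unless `atoms` is supplied).
#' @export
writeCoordsText <- function(traj, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# ecdyn-coords %d %d", nFrames(traj), nAtoms(traj)),
               con)
    for (f in seq_len(nFrames(traj)))
        utils::write.table(format(.frame(traj, f), digits = 17), con,
                           row.names = FALSE, col.names = FALSE,
                           quote = FALSE)
    invisible(path)
}

.readCoordsXYZ <- function(path) {
    hdr <- readLines(path, n = 1L)
    m <- regmatches(hdr, regexec("^# ecdyn-coords (\\d+) (\\d+)$", hdr))[[1]]
    if (length(m) != 3L)
        stop("not an ecdyn-coords file (bad header): ", path)
    nF <- as.integer(m[2]); nA <- as.integer(m[3])
    vals <- scan(path, skip = 1L, quiet = TRUE)
    if (length(vals) != nF * nA * 3L)
        stop(sprintf("expected %d coordinates, found %d in %s",
                     nF * nA * 3L, length(vals), path))
    # rows are atoms (x y z); regroup into frames-by-3N with xyz interleaved
    per_frame <- matrix(vals, ncol = 3L, byrow = TRUE)
    xyz <- matrix(0, nF, 3L * nA)
    for (f in seq_len(nF)) {
        blk <- per_frame[((f - 1L) * nA + 1L):(f * nA), , drop = FALSE]
        xyz[f, ] <- as.numeric(t(blk))
    }
    xyz
}

#' @rdname writeCoordsText
#' @param atoms optional atom table (data.frame); a generic one-CA-per-atom
#'   table is synthesized when omitted.
#' @export
readCoordsText <- function(path, atoms = NULL) {
    xyz <- .readCoordsXYZ(path)
    if (is.null(atoms)) atoms <- .syntheticAtomTable(ncol(xyz) %/% 3L)
    .trajectoryFromXYZ(xyz, atoms)
}

#' Select atoms with a minimal expression grammar
#'
#' Clauses are joined with `and`; each clause is one of `name <list>`,
#' `chain <list>`, `resid <ranges>`, `elem <list>` or `all`. Lists are
#' comma-separated; residue ranges are inclusive and use author numbering
#' (e.g. `resid 85-89` selects the PYR1 gate residues). Example:
#' `"name CA and chain A and resid 33-37"`.
#'
#' @param traj a [Trajectory-class] (or [SegmentEnsemble-class])
#' @param expr selection expression (character).
#' @return an [AtomSelection-class]; empty selections are an error.
#' @export
selectAtoms <- function(traj, expr) {
    atoms <- if (is(traj, "SegmentEnsemble")) atomTable(traj) else traj@atoms
    n <- nrow(atoms)
    keep <- rep(TRUE, n)
    clauses <- trimws(strsplit(expr, "\\band\\b")[[1]])
    for (cl in clauses) {
        if (cl == "" || tolower(cl) == "all") next
        parts <- strsplit(cl, "\\s+")[[1]]
        if (length(parts) < 2L)
            stop("cannot parse selection clause: '", cl, "'")
        key <- tolower(parts[1])
        val <- paste(parts[-1], collapse = "")
        items <- strsplit(val, ",")[[1]]
        keep <- keep & switch(key,
            name = atoms$name %in% items,
            chain = atoms$chain %in% items,
            elem = toupper(atoms$elem) %in% toupper(items),
            resid = {
                sel <- rep(FALSE, n)
                for (it in items) {
                    rng <- regmatches(it,
                        regexec("^(-?\\d+)(?:-(-?\\d+))?$", it))[[1]]
                    if (length(rng) == 0L)
                        stop("cannot parse residue range: '", it, "'")
                    lo <- as.integer(rng[2])
                    hi <- if (nzchar(rng[3])) as.integer(rng[3]) else lo
                    sel <- sel | (atoms$resid >= lo & atoms$resid <= hi)
                }
                sel
            },
            stop("unknown selection keyword: '", key, "'"))
    }
    idx <- which(keep)
    if (length(idx) == 0L)
        stop("selection '", expr, "' matches no atoms")
    new("AtomSelection", indices = as.integer(idx), label = expr,
        nAtomsSource = as.integer(n))
}

# Kabsch: proper rotation R and centroids aligning P (n x 3) onto Q (n x 3);
# apply as sweep(X, 2, cP) %*% R + cQ
.kabsch <- function(P, Q) {
    cP <- colMeans(P); cQ <- colMeans(Q)
    H <- crossprod(sweep(P, 2, cP), sweep(Q, 2, cQ))
    s <- svd(H)
    d <- sign(det(s$u %*% t(s$v)))
    if (d == 0) d <- 1
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    list(R = R, cP = cP, cQ = cQ)
}

.applyFit <- function(X, fit) {
    sweep(sweep(X, 2, fit$cP) %*% fit$R, 2, fit$cQ, "+")
}

.checkNotCollinear <- function(ref) {
    sv <- svd(sweep(ref, 2, colMeans(ref)))$d
    if (length(sv) < 2L || sv[2] <= 1e-8 * max(sv[1], 1))
        stop("reference atoms are collinear or degenerate; cannot superpose")
    invisible(TRUE)
}

#' Least-squares superposition of trajectory frames
#'
#' Rigid-body (Kabsch, proper rotation) superposition of every frame onto a
#' reference, fitting on the selected atoms and applying the transform to all
#' atoms. With `reference = "mean"` the fit is iterated: align to the current
#' mean structure, recompute the mean, align again (`iterations` passes),
#' which removes global translation/rotation before covariance analysis.
#'
#' @param traj a [Trajectory-class]
#' @param sel an [AtomSelection-class] (or integer indices); >= 3
#'   non-collinear atoms.
#' @param reference `"mean"` (default) or `"first"`.
#' @param iterations mean-reference refinement passes; `NULL` (default)
#'   iterates to the fixed point (largest coordinate shift below `tol`,
#'   at most 200 passes), which makes the operation idempotent.
#' @param tol convergence tolerance in angstroms for the iterated fit
#'   (default 1e-12).
#' @return the superposed [Trajectory-class]
#' @export
superposeFrames <- function(traj, sel = NULL,
                            reference = c("mean", "first"),
                            iterations = NULL, tol = 1e-12) {
    reference <- match.arg(reference)
    idx <- .resolveIndices(sel, nAtoms(traj))
    if (length(idx) < 3L) stop("need at least 3 atoms to superpose")
    co <- traj@coords
    nF <- dim(co)[1]
    alignTo <- function(co, ref) {
        .checkNotCollinear(ref)
        for (f in seq_len(nF)) {
            fit <- .kabsch(matrix(co[f, idx, ], ncol = 3L), ref)
            co[f, , ] <- .applyFit(matrix(co[f, , ], ncol = 3L), fit)
        }
        co
    }
    if (reference == "first") {
        co <- alignTo(co, matrix(co[1L, idx, ], ncol = 3L))
    } else {
        maxIter <- if (is.null(iterations)) 200L else max(1L, iterations)
        for (it in seq_len(maxIter)) {
            ref <- apply(co[, idx, , drop = FALSE], c(2, 3), mean)
            prev <- co
            co <- alignTo(co, ref)
            if (is.null(iterations) && max(abs(co - prev)) < tol) break
        }
    }
    initialize(traj, coords = co)
}

#' Root-mean-square deviation between coordinate sets
#'
#' @param a,b `N x 3` coordinate matrices or one-frame [Trajectory-class]
#'   objects of congruent shape.
#' @param sel optional [AtomSelection-class] or integer indices; the RMSD is
#'   computed over these atoms.
#' @param superpose if `TRUE`, Kabsch-fit `a` onto `b` over `sel` first.
#' @return RMSD in angstroms
#' @export
rmsd <- function(a, b, sel = NULL, superpose = FALSE) {
    toMat <- function(x) {
        if (is(x, "Trajectory")) {
            if (nFrames(x) != 1L)
                stop("rmsd() expects single structures; subset frames first")
            .frame(x, 1L)
        } else as.matrix(x)
    }
    A <- toMat(a); B <- toMat(b)
    if (!identical(dim(A), dim(B)))
        stop(sprintf("coordinate shapes differ: %d x %d vs %d x %d",
                     nrow(A), ncol(A), nrow(B), ncol(B)))
    idx <- .resolveIndices(sel, nrow(A))
    A <- A[idx, , drop = FALSE]; B <- B[idx, , drop = FALSE]
    if (superpose) A <- .applyFit(A, .kabsch(A, B))
    sqrt(mean(rowSums((A - B)^2)))
}

#' Split a trajectory into contiguous equal-length segments
#'
#' Slices `nSegments * segmentLength` frames from the tail (default), head,
#' or the exact whole trajectory, and cuts them into contiguous,
#' non-overlapping, equal-length segments for per-segment ECD statistics.
#'
#' @param traj a [Trajectory-class]
#' @param nSegments number of segments.
#' @param segmentLength frames per segment (>= 2).
#' @param take `"tail"` (default; analyze the end of the run, where the
#'   system is equilibrated), `"head"`, or `"all"` (requires
#'   `nSegments * segmentLength == nFrames`).
#' @return a [SegmentEnsemble-class]
#' @export
segmentTrajectory <- function(traj, nSegments, segmentLength,
                              take = c("tail", "head", "all")) {
    take <- match.arg(take)
    nSegments <- as.integer(nSegments)
    segmentLength <- as.integer(segmentLength)
    if (nSegments < 1L || segmentLength < 2L)
        stop("need nSegments >= 1 and segmentLength >= 2")
    need <- nSegments * segmentLength
    nF <- nFrames(traj)
    if (need > nF)
        stop(sprintf("insufficient frames: %d segments x %d frames = %d required, %d available",
                     nSegments, segmentLength, need, nF))
    if (take == "all" && need != nF)
        stop(sprintf("take = 'all' requires nSegments * segmentLength == nFrames (%d != %d)",
                     need, nF))
    start <- if (take == "tail") nF - need + 1L else 1L
    segs <- vector("list", nSegments)
    for (s in seq_len(nSegments)) {
        fr <- start + (s - 1L) * segmentLength + seq_len(segmentLength) - 1L
        segs[[s]] <- initialize(traj,
            coords = traj@coords[fr, , , drop = FALSE])
    }
    .logInfo("segmented %d frames into %d x %d (take = %s)", nF, nSegments,
             segmentLength, take)
    new("SegmentEnsemble", segments = segs, segmentLength = segmentLength)
}
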