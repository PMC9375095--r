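# ---- oligo objects ---------------------------------------------------------

.VALID_MODS  <- c("phosphate", "aldehyde", "oyo_link", "fluorophore", "none")
.VALID_ROLES <- c("circle_part", "arm", "tag", "detection", "padlock")

#' Construct a DNA oligonucleotide
#'
#' An oligo is a named DNA sequence (written 5'->3') with a 5'-end
#' modification and a functional role in the assay. Reporter tags, circle
#' parts and padlocks must carry a ligatable 5'-phosphate; arms (the
#' antibody-conjugated probes) carry the conjugation chemistry (aldehyde or
#' oyo-link). Detection oligos may carry a short 2'-OMe-U tail, recorded
#' separately from the DNA body so that all hybridization logic operates on
#' plain A/C/G/T.
#'
#' @param name identifier.
#' @param sequence DNA string over A/C/G/T, 5'->3'.
#' @param end5_mod one of `"phosphate"`, `"aldehyde"`, `"oyo_link"`,
#'   `"fluorophore"`, `"none"`.
#' @param role one of `"circle_part"`, `"arm"`, `"tag"`, `"detection"`,
#'   `"padlock"`.
#' @param tail optional non-DNA 3' tail (e.g. `"UUU"` on detection oligos).
#' @return an object of class `oligo`.
#' @export
oligo <- function(name, sequence, end5_mod = "none", role = "detection",
                  tail = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  end5_mod <- match.arg(end5_mod, .VALID_MODS)
  role     <- match.arg(role, .VALID_ROLES)
  sequence <- toupper(sequence)
  .check_dna(sequence, what = name)
  if (!nzchar(sequence))
    stop("oligo '", name, "': sequence must be non-empty")
  if (role %in% c("tag", "circle_part", "padlock") && end5_mod != "phosphate")
    stop("oligo '", name, "': role '", role,
         "' requires a 5'-phosphate (got '", end5_mod, "')")
  if (role == "arm" && !end5_mod %in% c("aldehyde", "oyo_link"))
    stop("oligo '", name, "': arms require end5_mod 'aldehyde' or 'oyo_link'")
  structure(list(name = name, sequence = sequence, end5_mod = end5_mod,
                 role = role, tail = tail),
            class = "oligo")
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo> %s [%s, 5'-%s] %d nt\n  %s%s\n",
              x$name, x$role, x$end5_mod, nchar(x$sequence), x$sequence,
              if (nzchar(x$tail)) paste0("-", x$tail) else ""))
  invisible(x)
}

.check_dna <- function(seq, what = "sequence") {
  if (!nzchar(seq)) return(invisible(TRUE))
  bad <- gregexpr("[^ACGT]", seq)[[1]]
  if (bad[1] != -1L)
    stop(what, ": non-ACGT character '",
         substr(seq, bad[1], bad[1]), "' at position ", bad[1])
  invisible(TRUE)
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick reverse complement over the A/C/G/T alphabet. An
#' involution: applying it twice returns the input. Non-ACGT characters are
#' rejected with a position report.
#'
#' @param seq DNA string (may be empty).
#' @return the reverse-complemented string.
#' @examples
#' reverse_complement("ACGT")  # palindrome -> "ACGT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  .check_dna(seq)
  if (!nzchar(seq)) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Load the packaged assay oligo set
#'
#' Reads the bundled FASTA fixture reproducing the published design table:
#' the two circle parts, arms A and B, reporter tags A and B, detection
#' oligos (DNA body plus U tail) and padlock probes A and B, with their
#' 5'-end modifications.
#'
#' @param path optional path to an alternative FASTA file whose headers carry
#'   `mod=`, `role=` and optional `tail=` fields.
#' @return a named list of [oligo] objects.
#' @export
molboolean_oligos <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "molboolean_oligos.fasta",
                        package = "molbool", mustWork = TRUE)
  read_oligo_fasta(path)
}

# ---- circles ---------------------------------------------------------------

.new_circle <- function(sequence, nicks = integer(0), nick_arms = character(0),
                        tags = character(0), sealed = length(nicks) == 0L,
                        exo_resistant = TRUE, origin = "assembled") {
  structure(list(sequence = sequence, nicks = as.integer(nicks),
                 nick_arms = nick_arms, tags_incorporated = sort(unique(tags)),
                 sealed = sealed, exo_resistant = exo_resistant,
                 origin = origin),
            class = "circle")
}

#' @export
print.circle <- function(x, ...) {
  cat(sprintf(
    "<circle> %d nt, %s, %d nick(s)%s, tags {%s} [%s]\n",
    nchar(x$sequence), if (x$sealed) "sealed" else "NOT sealed",
    length(x$nicks),
    if (length(x$nicks))
      paste0(" at ", paste(x$nicks, collapse = ",")) else "",
    paste(x$tags_incorporated, collapse = ","), x$origin))
  invisible(x)
}

#' Ligate the two circle parts into the information-receiver circle
#'
#' Both parts must be `circle_part` oligos carrying a 5'-phosphate; T4
#' ligation joins them part1 -> part2 into a covalently closed circle.
#' Circular molecules survive the subsequent exonuclease clean-up that
#' removes unligated linear oligos, so the result is flagged
#' exonuclease-resistant.
#'
#' @param part1,part2 [oligo] objects with role `"circle_part"`.
#' @return a sealed `circle` whose length is the sum of the part lengths.
#'   Sequence positions are 0-based modulo length, with the first base of
#'   `part1` as origin.
#' @export
assemble_circle <- function(part1, part2) {
  for (p in list(part1, part2)) {
    stopifnot(inherits(p, "oligo"))
    if (!nzchar(p$sequence)) stop("empty circle part '", p$name, "'")
    if (p$role != "circle_part")
      stop("oligo '", p$name, "' is not a circle part")
    if (p$end5_mod != "phosphate")
      stop("oligo '", p$name, "' not ligatable: missing 5'-phosphate")
  }
  .new_circle(paste0(part1$sequence, part2$sequence), origin = "assembled")
}

#' Survival of the exonuclease clean-up step
#'
#' Covalently closed circles survive combined exonuclease digestion; linear
#' species (unligated parts, free arms and tags) are removed.
#'
#' @param x a `circle` or an [oligo].
#' @return `TRUE` if the molecule survives digestion.
#' @export
survives_exonuclease <- function(x) {
  if (inherits(x, "circle")) return(isTRUE(x$exo_resistant) && x$sealed)
  FALSE
}

# ---- hybridization ---------------------------------------------------------

#' Longest exact reverse-complement match between two oligos
#'
#' Finds the longest stretch of `query` whose reverse complement occurs
#' contiguously in `target` (both read 5'->3'; the duplex is antiparallel).
#' With `anchor = "terminal5"` the match must include the query's first base;
#' with `"terminal3"` its last base; `"anywhere"` is unconstrained. A match
#' of length 0 is a valid result, not an error.
#'
#' All intervals are 0-based half-open. In the returned match, query base
#' `query_start` pairs with target base `target_end - 1` (antiparallel).
#'
#' @param query,target [oligo] objects or plain DNA strings.
#' @param anchor `"terminal5"`, `"terminal3"` or `"anywhere"`.
#' @return a list of class `hyb_match` with fields `length`, `query_start`,
#'   `query_end`, `target_start`, `target_end`, `orientation`.
#' @export
find_complement_match <- function(query, target,
                                  anchor = c("anywhere", "terminal5",
                                             "terminal3")) {
  anchor <- match.arg(anchor)
  q <- .as_seq(query); t <- .as_seq(target)
  .check_dna(q, "query"); .check_dna(t, "target")
  res <- switch(anchor,
    terminal5 = .match_terminal(q, t, from5 = TRUE),
    terminal3 = .match_terminal(q, t, from5 = FALSE),
    anywhere  = .match_anywhere(q, t))
  structure(c(res, list(orientation = "reverse-complement", anchor = anchor)),
            class = "hyb_match")
}

#' @export
print.hyb_match <- function(x, ...) {
  cat(sprintf(
    "<hyb match> %d nt (%s), query [%d,%d), target [%d,%d)\n",
    x$length, x$anchor, x$query_start, x$query_end,
    x$target_start, x$target_end))
  invisible(x)
}

.as_seq <- function(x) {
  if (inherits(x, "oligo")) x$sequence
  else if (inherits(x, "circle")) x$sequence
  else { stopifnot(is.character(x), length(x) == 1L); toupper(x) }
}

# Longest anchored match: grow from the anchored terminus. Growth is
# monotone (a k+1-mer match contains a k-mer match), so stop at first miss.
.match_terminal <- function(q, t, from5 = TRUE) {
  nq <- nchar(q)
  best <- 0L; pos <- NA_integer_
  if (nq > 0L && nzchar(t)) {
    for (k in seq_len(nq)) {
      sub <- if (from5) substr(q, 1L, k) else substr(q, nq - k + 1L, nq)
      hit <- regexpr(reverse_complement(sub), t, fixed = TRUE)
      if (hit == -1L) break
      best <- k; pos <- as.integer(hit) - 1L   # 0-based
    }
  }
  if (best == 0L)
    return(list(length = 0L, query_start = 0L, query_end = 0L,
                target_start = 0L, target_end = 0L))
  qs <- if (from5) 0L else nq - best
  list(length = best, query_start = qs, query_end = qs + best,
       target_start = pos, target_end = pos + best)
}

# Longest common substring between query and rc(target), by dynamic
# programming over suffix lengths (sequences here are <= a few hundred nt).
.match_anywhere <- function(q, t) {
  nq <- nchar(q)
  if (nq == 0L || !nzchar(t))
    return(list(length = 0L, query_start = 0L, query_end = 0L,
                target_start = 0L, target_end = 0L))
  rct <- reverse_complement(t)
  nt <- nchar(rct)
  qv <- strsplit(q, "")[[1]]; tv <- strsplit(rct, "")[[1]]
  prev <- integer(nt); best <- 0L; bq <- 0L; bt <- 0L
  for (i in seq_len(nq)) {
    eq <- (tv == qv[i])
    cur <- integer(nt)
    cur[eq] <- c(0L, prev)[which(eq)] + 1L
    if (max(cur) > best) {
      best <- max(cur); j <- which.max(cur)
      bq <- i - best; bt <- j - best        # 0-based starts in q and rc(t)
    }
    prev <- cur
  }
  if (best == 0L)
    return(list(length = 0L, query_start = 0L, query_end = 0L,
                target_start = 0L, target_end = 0L))
  # map interval on rc(target) back to target coordinates
  ts <- nt - (bt + best)
  list(length = best, query_start = bq, query_end = bq + best,
       target_start = ts, target_end = ts + best)
}

# All maximal exact rc matches of `arm` on the (circular) circle sequence,
# of at least `min_len` nt. Returns 0-based circle intervals (possibly
# wrapping) with the arm interval alongside.
.arm_footprints <- function(arm, circle_seq, min_len = 8L) {
  a <- .as_seq(arm)
  n <- nchar(circle_seq)
  dbl <- paste0(circle_seq, circle_seq)
  na <- nchar(a)
  cand <- list()
  for (i in seq_len(na)) {
    best <- 0L; pos <- NA_integer_
    k <- 0L
    while (i + k <= na) {
      sub <- substr(a, i, i + k)
      hit <- regexpr(reverse_complement(sub), dbl, fixed = TRUE)
      if (hit == -1L) break
      best <- k + 1L; pos <- as.integer(hit) - 1L
      k <- k + 1L
    }
    if (best >= min_len && !is.na(pos) && pos < n)
      cand[[length(cand) + 1L]] <-
        list(arm_start = i - 1L, len = best,
             circle_start = pos, circle_end = pos + best)
  }
  if (!length(cand)) return(cand)
  # keep only matches not contained in a longer match's arm interval
  s <- vapply(cand, `[[`, 0L, "arm_start")
  e <- s + vapply(cand, `[[`, 0L, "len")
  keep <- vapply(seq_along(cand), function(i) {
    !any(s <= s[i] & e >= e[i] & (s < s[i] | e > e[i]))
  }, TRUE)
  cand[keep]
}

# ---- nicking ---------------------------------------------------------------

#' Locate nickase cut sites on an arm-hybridized circle
#'
#' The nicking endonuclease only cuts double-stranded DNA, so nicks appear
#' only where an arm is hybridized, and only where the duplex contains the
#' recognition motif on the circle strand (default `GTCTC`, the Nt.BsmAI
#' site) -- which by design places every cut in the circle, never in the
#' probe. The cut falls `cut_offset` nucleotides 3' of the motif.
#'
#' @param circle a `circle`.
#' @param bound_arms list of arm [oligo]s currently hybridized to the circle.
#' @param motif recognition motif on the circle strand.
#' @param cut_offset nt between motif end and the cut.
#' @param min_anchor minimum duplex length considered a hybridization
#'   footprint.
#' @return the circle with `nicks` (0-based inter-base positions: a nick at
#'   p lies between bases p-1 and p, modulo length) and `nick_arms` filled
#'   in; one nick per arm with a motif-bearing footprint. Arms with no
#'   footprint contribute no nick (with a warning).
#' @export
find_nick_sites <- function(circle, bound_arms, motif = "GTCTC",
                            cut_offset = 1L, min_anchor = 8L) {
  stopifnot(inherits(circle, "circle"))
  if (inherits(bound_arms, "oligo")) bound_arms <- list(bound_arms)
  n <- nchar(circle$sequence)
  dbl <- paste0(circle$sequence, circle$sequence)
  nicks <- integer(0); arms <- character(0)
  for (arm in bound_arms) {
    fps <- .arm_footprints(arm, circle$sequence, min_len = min_anchor)
    if (!length(fps)) {
      warning("arm '", .oligo_name(arm), "' has no hybridization footprint")
      next
    }
    found <- FALSE
    for (fp in fps) {
      duplex <- substr(dbl, fp$circle_start + 1L, fp$circle_end)
      hit <- regexpr(motif, duplex, fixed = TRUE)
      if (hit != -1L) {
        m_end <- fp$circle_start + as.integer(hit) - 1L + nchar(motif)
        nicks <- c(nicks, (m_end + cut_offset) %% n)
        arms <- c(arms, .oligo_name(arm))
        found <- TRUE
        break                     # one nick per bound arm
      }
    }
    if (!found)
      warning("no '", motif, "' motif in the duplex of arm '",
              .oligo_name(arm), "'; no nick emitted")
  }
  circle$nicks <- as.integer(nicks)
  circle$nick_arms <- arms
  circle$sealed <- length(nicks) == 0L
  circle
}

.oligo_name <- function(x) if (inherits(x, "oligo")) x$name else "<seq>"

# ---- tag incorporation -----------------------------------------------------

# An arm's cognate tag is the tag whose reverse complement sits in the arm's
# loop-and-hairpin region.
.is_cognate <- function(tag, arm) {
  grepl(reverse_complement(.as_seq(tag)), .as_seq(arm), fixed = TRUE)
}

#' Incorporate reporter tags into a nicked circle
#'
#' Each nick was generated by a specific bound arm; a tag can only be
#' ligated into that nick if it is the arm's cognate tag (its reverse
#' complement lies in the arm's loop-and-hairpin region) and carries a
#' 5'-phosphate. Every resolved nick is sealed; the circle is sealed --
#' hence amplifiable -- only when all nicks were resolved. Tag content is
#' tracked both as a set and by splicing the tag sequence into the circle at
#' its nick, so downstream amplification carries the tag complement.
#'
#' @param circle a nicked `circle` (from [find_nick_sites]).
#' @param bound_arms the arms that generated the nicks.
#' @param offered_tags list of tag [oligo]s present in the reaction.
#' @return the updated circle; `tags_incorporated` holds the incorporated
#'   tag letters (`"A"`/`"B"` parsed from tag names, else full names).
#' @export
incorporate_tags <- function(circle, bound_arms, offered_tags) {
  stopifnot(inherits(circle, "circle"))
  if (length(circle$nicks) == 0L)
    stop("circle has no nick: tags can only enter a nicked circle")
  if (inherits(bound_arms, "oligo")) bound_arms <- list(bound_arms)
  if (inherits(offered_tags, "oligo")) offered_tags <- list(offered_tags)
  for (tg in offered_tags)
    if (inherits(tg, "oligo") && tg$end5_mod != "phosphate")
      stop("tag '", tg$name, "' not ligatable: missing 5'-phosphate")
  arm_by_name <- stats::setNames(bound_arms,
                                 vapply(bound_arms, .oligo_name, ""))
  resolved <- logical(length(circle$nicks))
  insert_seq <- character(length(circle$nicks))
  tags_in <- character(0)
  for (i in seq_along(circle$nicks)) {
    arm <- arm_by_name[[circle$nick_arms[i]]]
    if (is.null(arm)) next
    for (tg in offered_tags) {
      if (.is_cognate(tg, arm)) {
        resolved[i] <- TRUE
        insert_seq[i] <- .as_seq(tg)
        tags_in <- c(tags_in, .tag_letter(tg))
        break
      }
    }
  }
  # splice resolved tags into the sequence, highest position first so that
  # earlier insertions do not shift later nick coordinates
  ord <- order(circle$nicks[resolved], decreasing = TRUE)
  seq <- circle$sequence
  pos <- circle$nicks[resolved][ord]
  ins <- insert_seq[resolved][ord]
  for (j in seq_along(pos))
    seq <- paste0(substr(seq, 1L, pos[j]), ins[j],
                  substr(seq, pos[j] + 1L, nchar(seq)))
  circle$sequence <- seq
  circle$tags_incorporated <- sort(unique(c(circle$tags_incorporated,
                                            tags_in)))
  circle$nicks <- circle$nicks[!resolved]
  circle$nick_arms <- circle$nick_arms[!resolved]
  circle$sealed <- length(circle$nicks) == 0L
  circle
}

.tag_letter <- function(tg) {
  nm <- .oligo_name(tg)
  m <- regmatches(nm, regexpr("[AB]$", nm))
  if (length(m)) m else nm
}

# ---- amplification ---------------------------------------------------------

#' Rolling-circle amplification of a sealed circle
#'
#' Polymerization around the circle produces a single-stranded concatemer of
#' tandem repeats, each repeat the reverse complement of the circle read
#' once around from the origin. A circle left with any open nick is not
#' amplifiable.
#'
#' @param circle a sealed `circle`.
#' @param n_repeats number of tandem repeats (>= 0).
#' @return a list of class `concatemer` with `sequence`, `unit` and
#'   `n_repeats`; `tags` is inherited from the circle.
#' @export
amplify <- function(circle, n_repeats) {
  stopifnot(inherits(circle, "circle"))
  n_repeats <- as.integer(n_repeats)
  stopifnot(length(n_repeats) == 1L, n_repeats >= 0L)
  if (!circle$sealed)
    stop("not amplifiable: circle has ", length(circle$nicks),
         " open nick(s)")
  unit <- reverse_complement(circle$sequence)
  structure(list(sequence = strrep(unit, n_repeats), unit = unit,
                 n_repeats = n_repeats, tags = circle$tags_incorporated),
            class = "concatemer")
}

#' @export
print.concatemer <- function(x, ...) {
  cat(sprintf("<concatemer> %d x %d nt unit, tags {%s}\n",
              x$n_repeats, nchar(x$unit), paste(x$tags, collapse = ",")))
  invisible(x)
}

#' Count non-overlapping copies of a detection-oligo target in a concatemer
#'
#' A detection oligo hybridizes (full-length reverse-complement match)
#' wherever the concatemer contains the reverse complement of its DNA body,
#' i.e. once per repeat when its tag was incorporated.
#'
#' @param concatemer a `concatemer`.
#' @param probe detection [oligo] or DNA string.
#' @return integer count of non-overlapping binding sites.
#' @export
count_binding_sites <- function(concatemer, probe) {
  stopifnot(inherits(concatemer, "concatemer"))
  site <- reverse_complement(.as_seq(probe))
  if (!nzchar(concatemer$sequence) || !nzchar(site)) return(0L)
  hits <- gregexpr(site, concatemer$sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

# ---- padlock circularization ----------------------------------------------

#' Attempt template-directed circularization of a padlock probe
#'
#' The padlock's 5'- and 3'-terminal segments hybridize to the arm; ligation
#' closes the probe into a circle only when the two terminal footprints are
#' immediately adjacent on the arm (no gap, no overlap), juxtaposing the
#' 5'-phosphate and the 3'-OH. Adjacency depends only on which arm bases
#' pair with the padlock's first and last base, so it is insensitive to how
#' far each anchored match happens to extend away from the junction.
#'
#' @param padlock [oligo] with role `"padlock"` and a 5'-phosphate.
#' @param arm arm [oligo] serving as ligation template.
#' @return a sealed `circle` of the padlock's length, whose
#'   `tags_incorporated` records the tag sequence the padlock carries across
#'   its junction; or the string `"not_ligated"` when the ends do not meet.
#' @export
circularize_padlock <- function(padlock, arm) {
  stopifnot(inherits(padlock, "oligo"))
  if (padlock$role != "padlock")
    stop("oligo '", padlock$name, "' is not a padlock probe")
  if (padlock$end5_mod != "phosphate")
    stop("padlock '", padlock$name, "' not ligatable: missing 5'-phosphate")
  m5 <- find_complement_match(padlock, arm, "terminal5")
  m3 <- find_complement_match(padlock, arm, "terminal3")
  if (m5$length == 0L || m3$length == 0L) return("not_ligated")
  # arm base pairing padlock base 0 is target_end5 - 1; arm base pairing the
  # padlock's last base is target_start3. Ligatable iff juxtaposed.
  if (m3$target_start != m5$target_end) return("not_ligated")
  circ <- .new_circle(padlock$sequence, origin = "padlock")
  # the tag sequence is split across the junction; read circularly
  dbl <- paste0(circ$sequence, circ$sequence)
  tags <- character(0)
  for (tg in c("A", "B")) {
    tag_seq <- .PADLOCK_TAG_SEQS[[tg]]
    if (!is.null(tag_seq) && grepl(tag_seq, dbl, fixed = TRUE))
      tags <- c(tags, tg)
  }
  circ$tags_incorporated <- tags
  circ
}

# Tag bodies used to annotate padlock circles (same sequences as the
# packaged tag oligos; kept literal so circularization needs no fixture).
.PADLOCK_TAG_SEQS <- list(A = "CTGCAGCTATAAGTGCGGATG",
                          B = "CGTACGGGGCGGGTTAATTAC")

# ---- invariant report ------------------------------------------------------

#' Full oligo-design invariant report
#'
#' Recomputes, from sequences alone, the design arithmetic of the packaged
#' oligo set: circle assembly length, arm footprints and nick sites, the
#' tag-in-arm consistency, the padlock terminal footprints and linker
#' length, and the 8-case arm x tag specificity truth table.
#'
#' @param oligos named list from [molboolean_oligos].
#' @return a list of data frames: `$design`, `$truth_table`.
#' @export
oligo_check <- function(oligos = molboolean_oligos()) {
  circ <- assemble_circle(oligos$circle_part_1, oligos$circle_part_2)
  armA <- oligos$arm_A; armB <- oligos$arm_B
  tagA <- oligos$tag_A; tagB <- oligos$tag_B
  plA <- oligos$padlock_A; plB <- oligos$padlock_B

  fp <- function(pl, arm, anc) find_complement_match(pl, arm, anc)$length
  nick_n <- function(arms) length(find_nick_sites(circ, arms)$nicks)

  design <- data.frame(
    quantity = c("circle_length",
                 "padlock_A_length", "padlock_B_length",
                 "padlock_A_5p_footprint", "padlock_A_3p_footprint",
                 "padlock_B_5p_footprint", "padlock_B_3p_footprint",
                 "padlock_A_linker", "padlock_B_linker",
                 "tagA_rc_in_armA", "tagB_rc_in_armB",
                 "nicks_0_arms", "nicks_1_arm", "nicks_2_arms",
                 "padlock_A_on_armA_ligated", "padlock_A_on_armB_ligated"),
    value = c(nchar(circ$sequence),
              nchar(plA$sequence), nchar(plB$sequence),
              fp(plA, armA, "terminal5"), fp(plA, armA, "terminal3"),
              fp(plB, armB, "terminal5"), fp(plB, armB, "terminal3"),
              nchar(plA$sequence) - fp(plA, armA, "terminal5") -
                fp(plA, armA, "terminal3"),
              nchar(plB$sequence) - fp(plB, armB, "terminal5") -
                fp(plB, armB, "terminal3"),
              as.integer(.is_cognate(tagA, armA)),
              as.integer(.is_cognate(tagB, armB)),
              nick_n(list()), nick_n(list(armA)), nick_n(list(armA, armB)),
              as.integer(inherits(circularize_padlock(plA, armA), "circle")),
              as.integer(identical(circularize_padlock(plA, armB),
                                   "not_ligated"))))

  truth <- specificity_truth_table(oligos)
  list(design = design, truth_table = truth)
}

#' Arm x tag specificity truth table
#'
#' Enumerates the in-solution logic over bound-arm sets and offered-tag
#' sets: the circle is nicked only when an arm is present, and a sealed
#' (amplifiable) circle carries exactly the cognate tags of the arms that
#' were bound -- tags without their arm are never incorporated, and an
#' uncognate tag leaves its nick open so the circle stays non-amplifiable.
#'
#' @param oligos named list from [molboolean_oligos].
#' @param cases optional data frame with columns `arms`, `tags` (comma
#'   strings, `""` for none); the default enumerates the 8 informative
#'   combinations mirroring the published gel wells.
#' @return data frame with per-case nick count, sealed flag and incorporated
#'   tag set.
#' @export
specificity_truth_table <- function(oligos = molboolean_oligos(),
                                    cases = NULL) {
  circ0 <- assemble_circle(oligos$circle_part_1, oligos$circle_part_2)
  arm_set <- list(A = oligos$arm_A, B = oligos$arm_B)
  tag_set <- list(A = oligos$tag_A, B = oligos$tag_B)
  if (is.null(cases))
    cases <- data.frame(
      arms = c("",  "A", "B", "A,B", "A", "B", "A",  "B"),
      tags = c("A,B", "A", "B", "A,B", "B", "A", "A,B", "A,B"))
  res <- lapply(seq_len(nrow(cases)), function(i) {
    arms <- arm_set[strsplit(cases$arms[i], ",")[[1]]]
    tags <- tag_set[strsplit(cases$tags[i], ",")[[1]]]
    nicked <- find_nick_sites(circ0, arms)
    n_nicks <- length(nicked$nicks)
    if (n_nicks > 0L) nicked <- incorporate_tags(nicked, arms, tags)
    data.frame(arms = cases$arms[i], tags_offered = cases$tags[i],
               n_nicks = n_nicks, sealed = nicked$sealed,
               amplifiable = nicked$sealed,
               tags_incorporated = paste(nicked$tags_incorporated,
                                         collapse = ","))
  })
  do.call(rbind, res)
}
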