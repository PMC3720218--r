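# Worked-example molecule -----------------------------------------------------

#' The worked-example molecule for sphere and pair descriptors
#'
#' A 14-heavy-atom enyne ketone whose printed atom numbering makes the
#' sphere construction concrete for the target bond 8-9 (the C#C triple
#' bond): sphere 1 is atoms {5, 10}, sphere 2 is atoms {4, 6, 11, 14}, and
#' the element pair descriptor (sphere 2, distance 2, C-C) equals 4, counted
#' from the pairs 4-6, 4-8, 6-8 and 11-9. The structure is a reconstruction
#' consistent with those facts (the original figure is only available as an
#' image):
#'
#' `CH3(1)-CH2(2)-CH2(3)-CH2(4)-C(5)(=CH(6)-CH3(7))-C(8)#C(9)-C(10)(=O(14))-CH2(11)-CH2(12)-CH3(13)`
#'
#' Heavy atoms keep the numbering 1-14 (14 is the carbonyl oxygen);
#' hydrogens are appended after them.
#'
#' @return A [mol_graph()].
#' @export
#' @examples
#' env <- assign_spheres(example_molecule(), c(8, 9))
#' which(env$sphere == 1)  # atoms 5 and 10
example_molecule <- function() {
  atoms <- tibble(
    element = c("C", "C", "C", "C", "C", "C", "C", "C", "C", "C",
                "C", "C", "C", "O")
  )
  bonds <- tibble(
    from = c(1, 2, 3, 4, 5, 6, 5, 8, 9, 10, 10, 11, 12),
    to = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 14, 11, 12, 13),
    order = c(1, 1, 1, 1, 2, 1, 1, 3, 1, 2, 1, 1, 1)
  )
  filled <- fill_hydrogens(mutate(atoms, charge = 0L), bonds)
  mol_graph(filled$atoms, filled$bonds, name = "worked_example")
}
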