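test_that("cut plans follow the coil symmetry", {
  expect_equal(cut_plan("Bx")$axis, "vertical")
  expect_equal(cut_plan("Gzz")$axis, "vertical")
  expect_equal(cut_plan("By")$axis, "horizontal")
  expect_equal(cut_plan("Gyz")$axis, "horizontal")
  expect_equal(cut_plan("Bx")$expected_joints, 2L)
  expect_true(is.na(cut_plan("Bz")$expected_joints))
})

test_that("a single loop becomes a connected layout with a feed stub", {
  coil <- concentric_coil(0.4)
  set <- connect_loops(coil)
  expect_length(set, 1)
  b <- set$plane_pos
  expect_true(as.logical(board_connected(b)))
  expect_equal(board_crossings(b), 0)
  expect_equal(sum(vapply(b$traces, function(t) t$role == "loop", TRUE)), 1)
  expect_equal(nrow(b$terminals), 2)
})

test_that("concentric same-polarity loops spiral outermost-first with bridges", {
  coil <- concentric_coil(c(0.5, 0.4, 0.3, 0.2))
  set <- connect_loops(coil)
  b <- set$plane_pos
  expect_true(as.logical(board_connected(b)))
  expect_equal(board_crossings(b), 0)
  pol <- path_polarities(b)
  expect_equal(nrow(pol), 4)
  expect_true(all(pol$polarity == pol$traversed))
  # spiral order: loops visited outermost to innermost
  visited <- vapply(b$traces[b$path$id[
    vapply(b$path$id, function(i) b$traces[[i]]$role == "loop", TRUE)]],
    `[[`, 0L, "loop_id")
  areas <- vapply(coil$loops[visited], `[[`, 0, "area")
  expect_true(all(diff(areas) < 0))
  # front ring-to-ring bridges (excluding the hub tail) with identical
  # back-layer partners
  front_bridges <- Filter(function(t) t$layer == "F" && t$role == "bridge",
                          b$traces)
  expect_gte(length(front_bridges), 3)
  rets <- Filter(function(t) t$role == "bridge_ret", b$traces)
  expect_length(rets, length(front_bridges))
  for (r in rets)
    expect_identical(r$xy, b$traces[[r$partner_of]]$xy)
})

test_that("clockwise loops are traversed clockwise", {
  coil <- concentric_coil(c(0.45, 0.35, 0.25), polarity = -1L)
  b <- connect_loops(coil)$plane_pos
  pol <- path_polarities(b)
  expect_true(all(pol$traversed == -1L))
  expect_true(as.logical(board_connected(b)))
})

test_that("two separated nests are joined by a jumper crossing the cut once", {
  # opposite-polarity lobes left and right of the vertical symmetry axis
  loops <- c(
    lapply(c(0.25, 0.18, 0.11), function(r) {
      xy <- circle_loop(r, 0.5, center = c(-0.32, 0))
      list(vertices = xy, polarity = 1L, level = r, plane = 1L,
           area = pi * r^2)
    }),
    lapply(c(0.25, 0.18, 0.11), function(r) {
      xy <- circle_loop(r, 0.5, center = c(0.32, 0))
      xy <- xy[rev(seq_len(nrow(xy))), ]
      list(vertices = xy, polarity = -1L, level = -r, plane = 1L,
           area = pi * r^2)
    })
  )
  coil <- structure(list(loops = loops, turns = 6, level_step = 1,
                         plane_size = 1.4, separation = 1.0),
                    class = "discrete_coil")
  b <- connect_loops(coil, kind = "Bx")$plane_pos
  expect_true(as.logical(board_connected(b)))
  expect_equal(board_crossings(b), 0)
  pol <- path_polarities(b)
  expect_true(all(pol$polarity == pol$traversed))
  pair <- split_board(b, cut_plan("Bx"))
  expect_equal(pair$n_pad_pairs, 2)   # one front jumper + its back return
  merged <- merge_boards(pair)
  expect_true(as.logical(board_connected(merged, join_pads = TRUE)))
  expect_equal(layout_length(merged), layout_length(b), tolerance = 1e-9)
})

test_that("splitting severs traces into matched pad pairs and merge restores them", {
  coil <- concentric_coil(c(0.5, 0.4, 0.3))
  b <- connect_loops(coil, kind = "Bz")$plane_pos
  pair <- split_board(b, "vertical")
  expect_gt(pair$n_pad_pairs, 2)      # every ring straddles the axis
  expect_true(all(table(rbind(pair$a$pads, pair$b$pads)$pair) == 2))
  expect_false(as.logical(board_connected(pair$a)))
  merged <- merge_boards(pair)
  expect_true(as.logical(board_connected(merged, join_pads = TRUE)))
  expect_equal(layout_length(merged), layout_length(b), tolerance = 1e-9)
  # all traces on one side of the requested axis -> degenerate
  off <- concentric_coil(0.2)
  off$loops[[1]]$vertices[, 1] <- off$loops[[1]]$vertices[, 1] + 0.4
  b_off <- connect_loops(off)$plane_pos
  expect_error(split_board(b_off, "vertical"), "degenerate cut")
})

test_that("layout length sums both copper layers and exceeds the loops alone", {
  sq <- structure(list(loops = list(list(vertices = square_loop(1, 0.5),
                                         polarity = 1L, level = 1,
                                         plane = 1L, area = 1)),
                       turns = 1, level_step = 1, plane_size = 2.2,
                       separation = 1.0),
                  class = "discrete_coil")
  expect_equal(loops_length(sq), 4)
  b <- connect_loops(sq)$plane_pos
  expect_gt(layout_length(b), 4)
})

test_that("back-layer partners cancel the connection stray field", {
  coil <- concentric_coil(c(0.5, 0.42, 0.34, 0.26))
  b <- connect_loops(coil)$plane_pos
  ctr <- matrix(0, 1, 3)
  ideal <- polyline_field(lapply(coil$loops, `[[`, "vertices"), 1e-3, ctr)
  full <- layout_field(b, 1e-3, ctr)
  broken <- layout_field(b, 1e-3, ctr, include_partners = FALSE)
  pert <- sqrt(sum((full - ideal)^2))
  pert_broken <- sqrt(sum((broken - ideal)^2))
  expect_lt(pert, 0.005 * sqrt(sum(ideal^2)))
  expect_gt(pert_broken, pert)
})

test_that("the six-coil reference layouts satisfy the electrical invariants", {
  for (kind in c("Bz", "Bx")) {
    d <- small_design(kind)
    set <- small_board_set(kind)
    ctr <- matrix(0, 1, 3)
    coil_B <- sqrt(sum(polyline_field(d$coil, 1e-3, ctr)^2))
    for (nm in names(set)) {
      b <- set[[nm]]
      expect_true(as.logical(board_connected(b)), label = paste(kind, nm))
      pol <- path_polarities(b)
      expect_true(all(pol$polarity == pol$traversed),
                  label = paste(kind, nm, "polarity"))
      pl <- d$coil$loops[vapply(d$coil$loops, `[[`, 0L, "plane") ==
                           b$plane]
      ideal <- polyline_field(lapply(pl, `[[`, "vertices"), 1e-3, ctr)
      pert <- sqrt(sum((layout_field(b, 1e-3, ctr) - ideal)^2))
      expect_lt(pert, 0.005 * coil_B)
      pert_broken <- sqrt(sum((layout_field(b, 1e-3, ctr,
                                            include_partners = FALSE) -
                               ideal)^2))
      expect_gt(pert_broken, pert)
    }
    # connection overhead stays modest (richer multi-nest coils carry
    # longer jumper chains than single-nest ones)
    overhead <- layout_length(set) / loops_length(d$coil) - 1
    expect_lt(overhead, if (kind %in% c("Bz", "Gzz")) 0.10 else 0.25)
  }
})
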