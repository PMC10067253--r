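---
title: "Quantitative 3D occlusal contact and force analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 3D occlusal contact and force analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occlusal3d)
```

## The problem

Occlusal analysis asks where the teeth meet at maximal intercuspation, over
how much area, and with what force. Two established clinical records answer
complementary halves of the question:

* an **intraoral scan of articulating-paper marks** (the *SA* record): a
  colored triangle mesh in which each mark is a patch on the 3D tooth
  surface — it localizes contacts and measures the occlusal contact area
  (OCA, mm²) and contact number (OCN), but carries no forces;
* a **pressure-sensitive film record** (the *DP* record): a 2D map of
  contact points with per-contact area and absolute force in newtons — it
  quantifies load but loses the 3D tooth surface.

`occlusal3d` fuses the two: it segments the paper marks on the mesh, builds
an anatomical occlusal coordinate frame, registers the 2D film record onto
the projected 3D contacts, matches contacts across the records, and attaches
each film force to its 3D contact as a vector normal to the local contact
surface. The result is a per-contact and per-tooth force table — resultants
and x/y/z components — plus projections onto any clinical direction of
interest (mesiodistal, buccolingual, or arbitrary).

## Data model and units

Everything is in millimetres and newtons. A `colored_mesh` holds vertices,
triangles, per-vertex RGB (0–255) and optional per-vertex FDI tooth labels
(mandible 31–38, 41–48; 0 = unlabeled). PLY files carry no unit metadata;
coordinates are millimetres **by contract**. Tooth labels normally live in a
JSON sidecar so third-party scan exports need no modification; a per-vertex
integer PLY property `tooth` is accepted when present. The film record is a
plain table `id, u_mm, v_mm, area_mm2, force_N` (CSV or JSON): film
colorimetry-to-force calibration is upstream vendor software and out of
scope — forces are taken as given.

## The occlusal coordinate frame

Three manually picked landmarks define the frame (`landmark_set()`,
`build_occlusal_frame()`):

* origin — midpoint between the mesial line angles of the mandibular
  central incisors;
* the distobuccal cusp apexes of the left and right last molars.

The x–y plane is the mandibular occlusal plane through all three points.
The y-axis runs from the right to the left cusp (positive toward
patient-left); the x-axis is perpendicular to it in the plane, positive
anteriorly (this sign is fixed by requiring it to point from the molar line
toward the origin, which is unambiguous for any arch); z completes the
right-handed frame. With anatomically correct left/right labels, z then
points upward (toward the maxilla) automatically. Because a *swapped*
left/right labeling would silently flip z downward, an optional
`superior_ref` point (any maxillary-side point) arms a hard check that
raises an error instead. "Last molar" means the most distal molar present;
the landmark file, not the code, decides. Landmark picking itself is manual
by design — automatic cusp detection is out of scope.

## Contact segmentation

Clinically, marks are outlined by eye. Here the outline is a configurable
color rule (`mark_color()`), defaulting to HSV: hue within ±20° of the
paper color (red, 0°) **and** saturation ≥ 0.3. Tooth substance scans
near-achromatic (low saturation), so a saturation floor is robust to
exposure and white-balance differences between scanners; an RGB-distance
mode exists for unusual palettes. These thresholds are engineering
defaults, not measured constants — with a different paper color, set the
hue center accordingly.

Patches are connected components of marked vertices under shared-edge
adjacency (marks are *vertex* colors, so vertex adjacency — not face
adjacency — is the natural graph). Components below `min_area_mm2`
(default 0.05 mm², roughly single-vertex color noise at typical scan
resolution) are discarded but reported. Patch ids are assigned by
descending area, ties by smallest vertex index, so outputs are
reproducible.

Patch area uses fractional triangle weighting: a triangle with *m* marked
vertices contributes *m/3* of its area. This estimator is smooth at patch
borders and converges to the true region area under mesh refinement;
all-or-nothing counting is biased at the boundary and was rejected.
Sub-vertex (texture-resolution) boundaries and ink spread in saliva are
not modeled — spread biases SA areas upward relative to film areas, which
is visible in method comparisons but is a property of the medium, not of
the measurement code.

## Film cleanup and registration

Stray film points (handling artifacts, creases) sit far from the dental
arch. `remove_stray_points()` fits a quadratic arch `v = a·u² + b·u + c`
by least squares with one reweighting round (points beyond twice the
median absolute residual are dropped from a refit), then removes points
whose perpendicular distance to the final curve exceeds
`max_arch_distance_mm` (default 5 mm — the record's own scale suggests no
sharper value, and a manual exclusion list is available for parity with a
manual workflow). The perpendicular distance is computed by local
linearization, `|v − f(u)|/sqrt(1 + f'(u)²)`, rather than exact
point-to-parabola root-finding; for arch-typical curvature the two agree
to a few percent, far inside the threshold. With fewer than 6 points the
fit is unreliable and the map passes through with a warning. Inside
`run_pipeline()` the rule is applied in arch-aligned occlusal-plane
coordinates (u toward patient-left, v posterior), so it works no matter
how the film was oriented on the scanner bed; the standalone function
operates on native film coordinates as documented.

The film-to-plane overlay is a 2D similarity transform (scale, rotation,
translation) estimated in closed form from a handful of user-identified
correspondences — least squares on `sum |T(src) − dst|²`. Reflections are
deliberately excluded: both records are viewed from the occlusal
direction, so a reflected best fit means the film was digitized mirrored,
and the estimator errors out when the reflection branch fits better by
more than a factor 2 in RMS rather than silently flipping. Contact
matching is mutual nearest neighbor with a distance cutoff
(`max_match_distance_mm`, default 2 mm — small against the ≥ 3 mm spacing
of distinct occlusal contacts, large against registration residuals),
conflicts resolved greedily by ascending distance then smallest ids.
Mutual-NN was chosen over global optimal assignment for transparency; the
unmatched lists are always reported, never dropped.

## The force model

For each matched contact:

1. **Plane fit.** A total-least-squares plane through the patch vertices
   (in frame coordinates): the centroid plus the covariance eigenvector
   with the smallest eigenvalue. The normal is oriented into the +z
   hemisphere. Near-vertical patches (|n·ẑ| < 0.05) make that orientation
   meaningless, so the sign then follows the mean mesh vertex normal of
   the patch and the contact is flagged.
2. **Force vector.** The occlusal force on a mandibular contact acts
   *opposite* the oriented normal — into the tooth. Its magnitude is the
   matched film force. A force indicator segment runs from the plane
   center (base) to `base + magnitude·direction` (tip) at the glyph scale
   1 N = 1 mm (configurable; display only).
3. **Components.** `(Fx, Fy, Fz) = tip − base` in newtons. Endpoint
   labeling is a convention — defining components as tip minus base makes
   them the force vector's own coordinates and yields the clinically
   expected negative Fz (downward, into the mandible) at every contact
   whose normal orientation succeeded.

Per tooth, components are vector-summed. Two summary columns are reported
side by side because they answer different questions and are easy to
conflate: `resultant_N`, the norm of the vector sum (opposing horizontal
components cancel, as they should for net loading), and
`sum_of_magnitudes_N`, the scalar sum (total load transmitted through the
tooth; always ≥ the resultant). Regional roll-ups (anterior = FDI
positions 1–3, premolar 4–5, molar 6–8) evaluate the expected loading
gradient anterior < premolar < molar as strict boolean flags — on the
regional resultant, and per axis on summed *unsigned* components, since
left/right sides carry mirror-image transverse components whose signed
regional sum is near zero by symmetry. `project_direction()` projects
contact forces onto any unit direction (no silent normalization — a
non-unit direction is an error, because a silently normalized direction
would silently rescale forces).

## Method-agreement statistics

The agreement battery compares two measurement methods or sessions:
Shapiro–Wilk normality (delegated to the standard routine), two-sided
paired *t*, Pearson correlation with linear regression, and Bland–Altman
limits of agreement at the conventional bias ± 1.96 SD. Test–retest
reliability uses the intraclass correlation coefficient. The ICC has many
variants and reports rarely name one; this package defaults to ICC(2,1) —
two-way random effects, absolute agreement, single measurement — the
standard test–retest form, computed from the two-way ANOVA mean squares
with the F-based 95% confidence interval of Shrout & Fleiss. The model
name is printed in every result so the choice is auditable; ICC(3,1) is
available behind a flag. α = 0.05 throughout. The implementation is
cross-validated in the test suite against an independent reference
implementation (frozen values) and a hand-computed mean-squares oracle.

## The synthetic fixture generator

No public dataset pairs a colored scan with a film record, so the package
ships a ground-truthed generator (`generate_arch_mesh()`,
`paint_contacts()`, `derive_force_map()`, or `simulate_occlusion()` in one
call). It emulates:

* a mandibular arch band (intermolar width 52 mm, depth 44 mm — typical
  adult dimensions) meshed at a configurable edge length (default 0.2 mm,
  typical of intraoral-scan exports);
* 14 teeth as paraboloid crown caps with per-vertex FDI labels, each
  truncated near its cusp by a **planar wear facet** (drop 2 mm, tilt 8°
  from horizontal). Facets are the load-bearing surfaces: painted contact
  discs placed on them are exactly planar with a closed-form normal, so
  the whole pipeline's output can be compared to analytic truth at
  floating-point precision, not just approximately. Facet tilt azimuths
  use equal-weight x/y components with the transverse sign by side
  (patient-left vs right), so per-axis loading scales exactly with
  planned force and left/right molars carry opposite transverse
  components — a pattern also seen clinically;
* painted marks: vertices within the disc radius, mark color with small
  deterministic jitter inside the HSV window;
* a film record: contact centers projected onto the occlusal plane,
  mapped to native film axes, transformed by a known similarity, with
  optional Gaussian position jitter, multiplicative force noise, and
  stray off-arch points;
* two loading presets: `"normal"` (first molar carries the greatest
  force, anterior < premolar < molar) and `"bruxism"` (greatest force on
  the second molars, as with parafunctional grinding).

Ground truth records every contact's analytic normal, center, target area
πr², discretized painted area, and force; a single master seed drives all
randomness, and identical seeds reproduce fixtures bit for bit.

What the generator does **not** emulate: real crown morphology (cusps,
fissures), ink spreading, film shell deformation, scanner texture noise,
soft-tissue artifacts, or occlusal dynamics. Passing tests therefore
demonstrate that the geometry, registration, force algebra and statistics
are implemented correctly — not that color thresholds or matching radii
are optimal for any particular scanner or film; those remain
per-deployment configuration.

## Numerical choices and degenerate inputs

* Plane fits require ≥ 3 non-collinear points; collinearity is declared
  when the two smallest covariance eigenvalues both fall below 1e-12.
* Frame landmarks must span a triangle of area > 1e-6 mm².
* Similarity estimation needs ≥ 2 non-coincident correspondences; ties in
  matching break by smallest id; zero-magnitude forces yield a degenerate
  (zero-length) segment, not an error.
* Patch-area refinement: on a flat grid the disc-area error falls with
  the edge length (0.4 → 0.2 → 0.1 mm strictly decreasing in the test
  suite, ≤ 5% of πr² at 0.1 mm and well below 1% in practice).
* Report files round numeric output at 9 decimals and contain no
  timestamps, so identical seed + config reproduce byte-identical
  bundles.
* Test and acceptance runs use arch meshes at 0.3–0.5 mm edge length and
  a 0.1 mm flat grid for the area oracle — sizes chosen so the whole
  suite exercises every path in well under a minute of fixture time while
  keeping discretization error an order of magnitude below the asserted
  tolerances.

## A worked example

```{r example}
sim <- simulate_occlusion(arch_cfg(edge = 0.4), preset = "bruxism",
                          transform = similarity2d(1.1, 25, c(2, -3)),
                          seed = 7)
patches <- extract_patches(sim$fixture$mesh,
                           classify_marked_vertices(sim$fixture$mesh))
co <- tibble::tibble(
  patch_id = vapply(seq_len(nrow(sim$truth)), function(i) {
    d <- (patches$centroid_x - sim$truth$center_x[i])^2 +
      (patches$centroid_y - sim$truth$center_y[i])^2
    patches$patch_id[which.min(d)]
  }, integer(1)),
  point_id = seq_len(nrow(sim$truth)))
run <- run_pipeline(pipeline_config(
  mesh = sim$fixture$mesh, landmarks = sim$fixture$landmarks,
  force_map = sim$force_map, correspondences = co))
run$per_tooth[, c("tooth", "region", "Fx", "Fy", "Fz", "resultant_N")]
run$regional$ordering
```

The second molars (37, 47) dominate the per-tooth resultants under the
bruxism preset; all `Fz` are negative; the transverse components of the
left and right molars have opposite signs.

## Known limitations

* Static analysis at one jaw position (maximal intercuspation); dynamic
  occlusion over mandibular movement is out of scope.
* Landmarks and film correspondences are user-supplied picks.
* Force magnitudes are only as good as the film record; the package does
  not model film calibration or its compression-stiffness bias relative
  to articulating paper.
* Mark segmentation is color-thresholding, not learned; heavily stained
  or discolored dentition may need the RGB-distance mode or manual
  cleanup.
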