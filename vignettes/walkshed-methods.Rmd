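---
title: "Methods: neighbourhood walkability and access indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighbourhood walkability and access indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`walkshed` computes neighbourhood-level spatial indicators of urban design
and transport features on a pedestrian street network, at three nested
scales:

1. **Sample points** placed every 30 m along the walkable street network in
   populated areas act as proxies for the (unknown) spatial distribution of
   dwellings. Every point-level indicator is computed here.
2. **Hexagon neighbourhoods** (250 m flat-to-flat) carry the unweighted
   means of the member points' indicators; they are the unit for mapping
   and for between-city standardisation.
3. **City summaries** are population-weighted percentages over hexagons
   (share of residents with access, share of residents in neighbourhoods
   meeting a density threshold), suitable for benchmarking cities against
   each other.

The walking network is treated as undirected: one-way restrictions do not
bind pedestrians. All geometry is planar metres; geographic inputs must be
projected before use, because every threshold in the method (30 m, 250 m,
500 m, 1000 m, 1.5 ha) is metric.

# The indicator model

## Walkable catchments

The local environment of a sample point is its **1000 m walkable
catchment**: the portion of the street network reachable within 1000 m of
network distance (roughly a 13 minute walk), with partial edges trimmed
exactly at the cutoff. Rather than buffering the reached segments into a
sausage-shaped polygon, the catchment *area* is approximated by the set of
250 m population-grid cells that the reached network intersects — a
computationally tractable stand-in for the sausage-buffer construction.
Population and street-intersection densities are then

- `pop_density` = sum of member-cell populations / (number of cells x
  0.0625 km²), and
- `int_density` = count of intersections within the cutoff / the same area,

where an *intersection* is a network node of degree ≥ 3 (degree-2 nodes
are geometric vertices, not junctions). Two deliberate approximations are
documented here because they bias the densities in known directions:
member cells contribute their **whole** population even when only clipped
by the reached network (upward bias in sparse areas), and the far
endpoints of partially reached edges do not count as intersections.

## Destination access

The nearest network distance from each sample point to each destination
class is converted to a **binary access score**: 1 if the distance is
within 500 m (inclusive), 0 otherwise. Distances are searched up to a
3200 m cap and censored there; censored points score 0 at any sensible
threshold. The destination classes are healthy food markets, convenience
stores, public transport stops (three service-frequency variants, below),
and public open space entry points. Open-space entries are generated every
20 m along each polygon boundary and snapped to the network; the "large"
class keeps only spaces **strictly** larger than 1.5 ha.

## Service-frequency-aware transit access

From a GTFS feed, the package selects the representative weekday
(Monday–Friday day with the most scheduled departures; earliest day on
ties), pools every departure at each stop inside the daytime window
(07:00–19:00 by default), and takes the mean of consecutive
inter-departure gaps as the stop's **mean headway**. Stops classify as
"regular 30 min service" when the mean headway is ≤ 30 min and "regular
20 min service" when ≤ 20 min; stops with fewer than two windowed
departures have undefined headway and fail both classes. The mean-of-gaps
estimator was chosen over `window length / departure count` because the
latter understates gaps at the window edges. Deduplication is by departure
time at the stop, so duplicated schedules (the same service imported twice
under different route ids) do not distort headways.

## Composite indicators

- **Daily living score** (0–3): sum of the binary access scores for
  healthy food, convenience, and *any* public transport stop.
- **Walkability index**: `z(pop_density) + z(int_density) +
  z(daily_living)`, equal-weighted standardised scores. Within-city
  scores standardise against the city's own distribution; between-city
  scores standardise against the pooled hexagons of all supplied cities,
  so zero means the all-cities average. Z-scores use the population
  (n-denominator) standard deviation.
- **Threshold scenarios**: scenario A flags neighbourhoods whose density
  reaches the threshold associated with an 80% probability of walking for
  transport; scenario B the (higher) threshold for at least a 15% relative
  reduction in insufficient physical activity. Defaults are the lower
  bounds of the published 95% CIs — population density 4790 (A) and 5677
  (B) persons/km², intersection density 90 (A) and 106 (B) per km² — and
  are configurable. "Reaching" is inclusive (≥).

# Tunable parameters

| Parameter | Default | Unit | Notes |
|---|---|---|---|
| sample interval | 30 | m | dwelling-proxy spacing along edges |
| catchment cutoff | 1000 | m | ~13 min walk |
| access threshold | 500 | m | inclusive |
| distance cap | 3200 | m | censoring bound for nearest-distance search |
| grid cell size | 250 | m | population grid |
| hex width | 250 | m | flat-to-flat |
| POS entry spacing | 20 | m | along polygon boundary |
| large POS class | 1.5 | ha | strictly greater than |
| snap tolerance | 500 | m | destinations farther away are dropped |
| GTFS window | 07:00–19:00 | — | "daytime" |
| scenario A / B | 4790/90, 5677/106 | persons, intersections per km² | lower 95% CI bounds |

Several of these (entry spacing, snap tolerance, cap, daytime window,
representative-weekday rule) are not fixed by the indicator definitions;
the defaults above are this package's declared choices, exposed as
arguments so other conventions can be swapped in.

# Numerical and geometric conventions

- **Grid and hex anchoring.** Both lattices anchor at the south-west
  corner of the region's bounding box; they are deterministic functions of
  the region, so runs reproduce exactly. Hexagons are flat-topped with
  250 m flat-to-flat width (area `(√3/2)·250² ≈ 5.4 ha`, comparable to a
  grid cell); the orientation and the reading of "250 m" are package
  conventions, as a hexagon size can be quoted corner-to-corner or
  flat-to-flat.
- **Sample-point offsets** are measured from the lower-node-id endpoint of
  each edge, so outputs do not depend on edge direction in the input
  file. Offsets are `interval, 2·interval, …, k·interval` with
  `k = floor((L − 1 mm)/interval)`; the millimetre epsilon keeps a point
  off the far node when the length is an exact multiple, and edges with
  `k = 0` get a single midpoint point so every edge is represented.
- **Mid-edge origins** reach the network through either endpoint of their
  edge; distances are exact (loops included) because any path out of the
  edge passes an endpoint. On the origin's own edge the direct along-edge
  distance is also considered.
- **Cell membership** of a street segment uses half-open `[min, max)`
  squares: a segment running exactly along a shared cell boundary counts
  once, in the cell on the increasing side, and membership requires a
  positive-length overlap (single-point touches do not count).
- **Ties.** Snapping ties go to the lower edge id; equal-size network
  components to the one containing the smallest node id; hexagon boundary
  points to the smallest hex id (hexagon tilings are the Voronoi diagrams
  of their centroids, so nearest-centroid assignment is exact).
- **Polygon intersection** (study region = administrative boundary ∩
  urban extent) uses Sutherland–Hodgman clipping, which requires the
  urban-extent polygon to be convex. Rectangular or hexagonal extents
  satisfy this; arbitrary concave extents would need pre-processing in a
  GIS.

# The synthetic-city generator

The generator exists so that every downstream stage is testable offline.
It emulates, under a single integer seed with one independent stream per
layer:

- **connected planar street networks** — a regular lattice (`grid`) or a
  perturbed lattice with up to 30% positional noise and a fraction of
  edges removed while preserving connectivity (`organic`);
- **radially decaying population** — a seeded multinomial draw over the
  250 m grid with exponential expected weights (`exp(-gradient · r_km)`),
  conserving the total exactly;
- **clustered amenities** — points placed on or within 20 m of edges,
  drawn near seeded cluster centres with probability `cluster_factor`;
- **mixed-size open spaces** — axis-aligned rectangles within 5% of the
  requested areas (sufficient for the area-class logic);
- **fixed-headway weekday transit** — a minimal GTFS feed with departures
  every `transit_headway_min` minutes from 06:00 to 22:00, weekdays only.

The defaults (2 km extent, 250 m blocks, 20,000 residents, decay rate
1/km, 20 min headway) describe a compact mid-sized test city and are held
fixed across the test suite. What the generator does **not** emulate:
real OSM tagging and its classification noise, kerbs/crossings and other
micro-scale walkability barriers, curved street geometry, informal
transit, and land-use correlation between amenities and population. Tests
passing on synthetic cities therefore validate the *computational engine*
— distances, catchments, classification, aggregation — not the fidelity
of any specific open-data extract.

# Verification strategy

Three layers of checks back the implementation:

- **Independent oracles.** Shortest distances are compared against a
  plain Bellman–Ford relaxation over the edge list (with a pseudo-node
  splitting the origin's edge); reached length against dense per-metre
  labelling; catchment cells against dense point-sampling membership; and
  nearest destination distances against a per-destination scan. These run
  over batteries of seeded grid, organic and random-geometric networks.
- **Planted-parameter recovery.** Long "ribbon" cities with uniform
  population are built so that a known fraction *p* of street length lies
  within 500 m of a market; the population-weighted city access
  percentage must recover 100·p within 2 points for
  p ∈ {0, 0.25, 0.5, 0.75, 1}.
- **Worked-example aggregation.** The bundled 25-city benchmark table is
  aggregated with `group_summary()` and compared against its published
  income-group and total summary figures. Only summary rows that are
  exact unweighted means of the printed per-city cells are asserted; the
  source's transit and open-space summary rows do not equal simple means
  of their printed columns (their aggregation rule is unstated), so they
  are not used as checks. The per-city values themselves are inputs, not
  reproduction targets — recomputing them would require full-scale
  city-specific network, population, destination and schedule data.

Problem sizes in the default test run (networks of 25–100 nodes, 12 km
ribbons, 2 km demo cities with ~1000 sample points) were chosen to
exercise every code path while keeping the whole suite in the order of a
couple of minutes on one CPU.

# Known limitations

- Whole-cell population inclusion overestimates catchment population
  where the grid is coarse relative to the street pattern.
- Between-city standardisation pools hexagons unweighted; a
  population-weighted pooling is a defensible alternative and can be
  obtained by standardising externally with `standardise(values,
  reference = ...)`.
- The GTFS handling applies `calendar.txt` weekday flags and expands
  `frequencies.txt`, but ignores `calendar_dates.txt` exceptions: the
  representative weekday is an abstract day, not a calendar date, so
  date-specific exceptions have no well-defined meaning here. Feeds whose
  weekday service is encoded *only* through `calendar_dates` will appear
  serviceless.
- Edge geometry is straight between endpoints; supplied `length_m` longer
  than the straight-line distance is honoured for routing, but cell
  intersection uses the straight chord.
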