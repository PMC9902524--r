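# walkshed

Neighbourhood spatial indicators of walkability and amenity access on
pedestrian street networks.

City planners and urban-health researchers need two views of the same
evidence: *within-city* maps that reveal which neighbourhoods lack
walkable access to daily amenities, and *between-city* benchmarks that
compare cities on a consistent footing. `walkshed` computes both from
format-neutral open inputs — a pedestrian network (node/edge tables), a
250 m population grid, destination point/polygon layers, and optionally a
GTFS transit schedule — entirely in planar metric coordinates.

## What it computes

For sample points placed every 30 m along the street network in populated
areas (a proxy for dwellings):

- **1000 m walkable catchment**: the reachable street network within
  1000 m, intersected with the 250 m grid — a tractable approximation of a
  sausage buffer — giving population density and street-intersection
  density (intersections = nodes of degree ≥ 3);
- **binary 500 m access** to healthy food markets, convenience stores,
  public transport stops (any / mean weekday daytime headway ≤ 30 min /
  ≤ 20 min, from GTFS), and public open space entry points (any /
  strictly > 1.5 ha);
- **daily living score** (0–3): food + convenience + any transit access;
- **walkability index**: `z(pop density) + z(intersection density) +
  z(daily living)`, standardised within the city or against all pooled
  cities (between-city z-scores; zero = global average);
- **threshold scenarios**: share of population in neighbourhoods whose
  densities reach the scenario A thresholds (80% probability of walking
  for transport: 4790 persons/km², 90 intersections/km²) or the scenario B
  thresholds (≥ 15% relative reduction in insufficient physical activity:
  5677 persons/km², 106 intersections/km²).

Point indicators are averaged to 250 m hexagon neighbourhoods, and city
summaries are population-weighted percentages over hexagons. A
deterministic seeded synthetic-city generator (street network, population
grid, clustered amenities, open space, GTFS feed) makes the entire
pipeline testable offline, and a bundled 25-city benchmark table supports
the income-group aggregation worked example.

## Worked example

```r
library(walkshed)

# a complete synthetic city from one seed
spec  <- city_spec(seed = 7, n_stops = 6)
city  <- generate_city(spec, dir = tempfile())
layers <- build_city_layers(city, gtfs_dir = city$gtfs_dir)
run   <- analyse_city(city$network, city$grid, city$region, layers,
                      city = "synthetic-7")

nrow(run$points)
#> [1] 1024
round(run$city$pct_access_food, 1)
#> [1] 50.8
round(run$city$pct_access_pt_any, 1)
#> [1] 25.7
```

1024 sample points cover the 36 km network; 50.8% of the city's residents
(population-weighted over hexagon neighbourhoods) live within a 500 m walk
of a healthy food market, and 25.7% within 500 m of a transit stop — the
six stops cluster near seeded centres, so much of the city is out of
reach.

The benchmark aggregation reproduces published group summaries from the
bundled 25-city table:

```r
gs <- group_summary(city_benchmark_table())
round(gs$mean[gs$group == "middle" & gs$indicator == "pct_access_food"], 1)
#> [1] 25.3
round(gs$mean[gs$group == "total"  & gs$indicator == "pct_access_food"], 1)
#> [1] 36.4
```

A thin command-line wrapper covers the common flows:

```sh
Rscript inst/cli/walkshed.R synth --seed 3 --dir my_city
Rscript inst/cli/walkshed.R run --city my_city --out my_city_results
Rscript inst/cli/walkshed.R benchmark \
    --cities inst/extdata/city_benchmark.csv --out bench
```

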