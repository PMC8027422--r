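# Message schema for wiring real hardware

The package closes the trapping/imaging loop with in-process calls. The
original instrument class splits the loop across two machines connected by
UDP; anyone wiring `holotwin` to real hardware can use the message shapes
below (JSON over any transport), which mirror the package's tibble columns.

## Trap command (interface -> holographic engine)

```json
{
  "type": "traps",
  "time": 1.234,
  "traps": [{"x": 1.0, "y": -2.0, "z": 5.0, "w": 1.0}],
  "rigid": {"rotate_z_deg": 0, "scale": 1, "translate": [0, 0, 0]}
}
```

Coordinates are micrometres in imaging space; the engine applies the
calibration model (`calibration.json`, see `write_calibration()`) before
computing the mask with `gsw_optimize()`. An empty `traps` list switches
all traps off.

## Feature update (holographic engine -> interface)

```json
{
  "type": "features",
  "frame": 17,
  "time": 0.425,
  "objects": [
    {"id": 3, "x": 1.0, "y": -2.0, "z": 5.0,
     "l": 3.1, "b": 1.0, "ex": 0.9, "ey": 0.4, "ez": 0.1,
     "voxel_count": 250, "speed": 18.5}
  ]
}
```

One object per row of `segment_volume()` plus the track id and speed from
`link_tracks()`.

## Mesh update (live-mesh display mode)

```json
{
  "type": "mesh",
  "frame": 17,
  "iso_level": 0.3,
  "vertices": [[x, y, z]],
  "triangles": [[i, j, k]]
}
```

Vertex coordinates are micrometres; triangle indices are 0-based on the
wire (the package's `surface_mesh` uses 1-based indices internally, and
`write_mesh_ply()` already emits 0-based).

All lengths are micrometres, times seconds, little-endian when binary.
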