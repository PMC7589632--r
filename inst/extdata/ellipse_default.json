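{"center":[0,0],"semi_axes":[73.597463,177.598292],"tilt":45,"anchors":{"A":297.72,"B":237.72,"C":177.72,"D":131.1,"E":84.49,"F":41.1,"G":357.72}}
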