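# Published coordinates of nine homozygous segments shared, within ROH,
# by more than 30% of Italian Holstein cows of a production subgroup.
# Coordinates are 1-based bp on the bovine autosomes; length_mb is the
# reported segment length in Mb (2 decimals), under the convention
# length = to_bp - from_bp.
subgroup_set	chrom	from_bp	to_bp	length_mb
DM	4	50870642	50985356	0.11
DM	5	13303423	13731438	0.43
GP,TR	10	30363081	30990261	0.63
AS,DM,GP,PR,TR	10	34352857	36318731	1.97
DM,GP,PR	10	62853400	63574350	0.72
DM,GP,PR	10	74652896	75972046	1.32
DM,GP,PR	10	78402871	79477825	1.07
AS,GP,PR,TR	16	80385720	81672961	1.29
AS,DM,GP,TR	20	31595896	33309782	1.71
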