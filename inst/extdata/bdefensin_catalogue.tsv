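symbol	chromosome	start	end	reference_copies	assay_group	orthologue
DEFB43	chr8	7,449,722	7,456,717	1	DEFB43	HBD131A
DEFB134	chr8	7,469,680	7,473,928	1	DEFB134	HBD134
DEFB136	chr8	7,499,869	7,500,896	1	DEFB136	HBD136
DEFB132-1	chr13	60,755,471	60,757,652	1	DEFB132-1	HBD132
DEFB129-2	chr13	60,772,966	60,775,142	1	DEFB129-2	HBD129
DEFB128	chr13	60,785,898	60,787,480	1	DEFB128	HBD128
DEFB127	chr13	60,793,742	60,796,520	1	DEFB127	HBD127
DEFB126	chr13	60,806,515	60,811,042	1	DEFB126	HBD126
DEFB125A	chr13	60,828,555	60,835,043	1	DEFB125A	HBD125
DEFB125	chr13	60,828,987	60,829,208	1	DEFB125	HBD125
DEFB115	chr13	60,873,647	60,884,399	1	DEFB115	HBD115
DEFB29	chr13	60,893,940	60,905,009	1	DEFB29	none
DEFB116	chr13	60,920,317	60,925,563	1	DEFB116	HBD116
DEFB117	chr13	60,956,394	60,959,265	1	DEFB117	HBD118
DEFB118	chr13	60,979,467	60,979,700	1	DEFB118	HBD118
DEFB119-1	chr13	60,981,163	60,990,988	1	DEFB119-1	HBD119
DEFB119-2	chr13	60,989,366	60,990,988	1	DEFB119-2	none
DEFB121	chr13	61,007,870	61,009,276	1	DEFB121	HBD121
DEFB122A	chr13	61,019,572	61,023,625	1	DEFB122A	none
DEFB122	chr13	61,030,365	61,034,955	1	DEFB122	none
DEFB123-2	chr13	61,038,268	61,052,092	1	DEFB123-2	HBD123
DEFB123-1	chr13	61,041,375	61,051,806	1	DEFB123-1	HBD123
DEFB124	chr13	61,067,234	61,069,998	1	DEFB124	HBD124
DEFB114	chr23	22,612,721	22,615,376	1	DEFB114	HBD114
DEFB113	chr23	22,632,551	22,635,067	1	DEFB113	HBD113
DEFB110-1	chr23	22,644,099	22,656,635	1	DEFB110-1	HBD110
DEFB110-2	chr23	22,651,406	22,656,635	1	DEFB110-2	none
DEFB112	chr23	22,662,983	22,671,406	1	DEFB112	HBD112
DEFB1-2	chr27	5,960,716	5,968,525	1	DEFB1-2	none
TAP	chr27	6,013,830	6,015,648	1	TAP	none
DEFB103B	chr27	6,023,993	6,025,303	3	DEFB103	HBD103B/HBD-like
SPAG11B	chr27	6,045,534	6,050,941	1	SPAG11B	H-SPAG11B
DEFB104	chr27	6,069,928	6,074,858	1	DEFB104	HBD104A
DEFB106A	chr27	6,076,779	6,079,838	1	DEFB106A	HBD106B-2
DEFB15	chr27	6,076,989	6,079,896	1	DEFB15	HBD106B-2
DEFB105	chr27	6,082,209	6,084,799	1	DEFB105	HBD105A
DEFB107A	chr27	6,090,910	6,095,691	1	DEFB107A	HBD107A/HBD106B-1
DEFB130-1	chr27	6,192,946	6,196,744	1	DEFB130-1	HBD130A
LAP	chr27	6,234,006	6,235,870	1	LAP	none
DEFB33	chr27	6,238,997	6,242,941	1	DEFB33	none
DEFB13	chr27	6,326,696	6,328,616	1	DEFB13	none
DEFB103A	chr27	6,432,334	6,433,571	3	DEFB103	HBD103B/HBD-like
DEFB10	chr27	6,596,623	6,598,299	1	DEFB10	none
DEFB3	chr27	6,676,309	6,723,692	1	DEFB3	none
DEFB7	chr27	6,676,383	6,678,273	1	DEFB7	none
DEFB6	chr27	6,676,387	6,996,057	1	DEFB6	none
DEFB9	chr27	6,676,540	6,678,161	1	DEFB9	none
DEFB1-1	chr27	6,721,772	6,723,692	1	DEFB1-1	HBD1
DEFB402	chr27	6,855,327	6,856,946	1	DEFB402	none
DEFB4A	chr27	7,138,963	7,140,882	1	DEFB4A	none
DEFB5	chr27	7,139,081	7,140,848	1	DEFB5	none
EBD	chr27	7,165,176	7,180,422	1	EBD	none
DEFB108B	chr27	7,272,455	7,275,948	1	DEFB108B	HBD108B
DEFB109	chr27	7,281,838	7,289,252	1	DEFB109	HBD109A
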