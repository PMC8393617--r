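Synthetic example of the PhysioNet CAP event-list dialect (not from any
real recording); columns: Sleep Stage, Position, Time, Event, Duration, Location.

Sleep Stage	Position	Time [hh:mm:ss]	Event	Duration[s]	Location
S2	Supine	23:59:30	SLEEP-S2	30	C4-A1
S2	Supine	00:00:00	SLEEP-S2	30	C4-A1
S2	Supine	00:00:05	MCAP-A1	8	C4-A1
S2	Supine	00:00:30	SLEEP-S2	30	C4-A1
S2	Supine	00:00:35	MCAP-A2	6	C4-A1
S3	Supine	00:01:00	SLEEP-S3	30	C4-A1
S3	Supine	00:01:05	MCAP-A1	10	C4-A1
REM	Supine	00:01:30	SLEEP-REM	30	C4-A1
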