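label,threshold
friend,14.90
today,14.38
think,16.17
luggage,14.06
how,14.53
good,14.87
doctor,17.55
afternoon,16.33
one,16.35
hello,15.23
egg,14.58
me,14.42
ok,15.06
where,15.42
support,14.38
lighter,14.83
morning,14.93
dusk,17.26
sky,16.11
home,14.92
airport,15.27
consign,15.77
find,16.56
we,14.58
fever,16.38
yesterday,14.82
say,15.14
evening,19.03
return,17.28
who,14.62
take off,15.25
why,17.24
Shenyang,15.23
teacher,14.27
communicate,16.46
ask,14.12
happy,16.47
go,14.23
toilet,15.30
time,16.17
ID card,15.29
help,13.49
like,15.63
how to go,17.26
do,16.37
noon,14.67
late,17.93
refund,16.88
miss,15.19
terminal,12.99
China,15.16
listen,13.22
not found,14.62
[],21.99
thanks,16.33
meat,15.39
ticket,15.98
change,13.60
watch,19.03
Liaoning,15.29
come,16.15
tomorrow,15.76
sorry,16.59
contact,14.64
worry,14.98
flight,15.10
key,14.18
world,15.29
love,15.38
confiscate,16.45
it's ok,14.73
you,14.76
how,16.01
delay,14.99
knife,14.99
Beijing,15.72
want,14.53
everybody,14.89
eat,14.96
what,14.26
question,14.72
excuse,16.32
cigarette,13.76
charge,14.58
drink,15.76
(early) morning,15.34
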